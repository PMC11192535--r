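test_that("peptide matching is exact contiguous substring alignment", {
  r <- match_peptides("MKTRVLAAK", c("KTR", "VLA", "AAK", "WWW"))
  expect_equal(r$n_distinct_matched, 3L)
  expect_setequal(r$matched, c("KTR", "VLA", "AAK"))
  expect_equal(match_peptides("MKTR", "MKTR")$n_distinct_matched, 1L)
  expect_equal(match_peptides("MKVLAK", "VIA")$n_distinct_matched, 0L)
  expect_equal(match_peptides("MKVLAK", "VIA",
                              il_equivalence = TRUE)$n_distinct_matched, 1L)
  expect_error(match_peptides("MKR", c("MK", "")), "empty peptide")
  # duplicate observations of the same peptide count once
  expect_equal(match_peptides("MKTR", c("KT", "KT", "KT"))$n_distinct_matched, 1L)
})

test_that("match_peptides agrees with a naive quadratic substring scan", {
  set.seed(31)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:1000) {
    prot <- paste(sample(aas, sample(10:60, 1), replace = TRUE), collapse = "")
    pep <- if (runif(1) < 0.5) {
      start <- sample(nchar(prot) - 5, 1)   # embedded peptide
      substr(prot, start, start + sample(3:5, 1))
    } else paste(sample(aas, sample(3:8, 1), replace = TRUE), collapse = "")
    il <- runif(1) < 0.5
    got <- match_peptides(prot, pep, il)$n_distinct_matched == 1
    expect_identical(got, naive_substring_match(prot, pep, il),
                     label = paste(prot, pep, il))
  }
})

test_that("peptide_support counts distinct matched peptides per protein and flags shared ones", {
  proteins <- c(p1 = "MKTRVLAAK", p2 = "GGVLAGG")
  tab <- data.frame(peptide = c("VLA", "VLA", "KTR"),
                    spectrum_count = c(5, 2, 1))
  s <- peptide_support(proteins, tab)
  expect_equal(s$n_distinct_matched[s$protein_id == "p1"], 2L)
  expect_equal(s$n_distinct_matched[s$protein_id == "p2"], 1L)
  expect_equal(s$n_shared_peptides, c(1L, 1L))  # VLA matches both
  expect_equal(s$total_spectra[s$protein_id == "p1"], 8)
})

test_that("venom-protein calls require expression AND >= min distinct peptides", {
  sup <- data.frame(protein_id = c("g1", "g2", "g3"),
                    n_distinct_matched = c(3L, 2L, 10L),
                    n_shared_peptides = 0L,
                    total_spectra = c(3, 50, 10))
  expressed <- c("g1", "g2")
  calls <- call_venom_proteins(expressed, sup, min_peptides = 3)
  expect_identical(calls$gene_id, "g1")      # boundary inclusive at 3
  # g2 has 50 spectra but only 2 distinct peptides; g3 is not expressed
  expect_false("g2" %in% calls$gene_id)
  expect_false("g3" %in% calls$gene_id)
  expect_error(call_venom_proteins(expressed, sup, 3,
                                   gene_universe = c("g1", "g2")),
               "unknown gene.*g3")
})

test_that("venom evidence is monotone: more peptides never remove a call, stricter cutoff never adds one", {
  set.seed(17)
  proteins <- c(gA = "MKTRVLAAKDDEFK", gB = "GGHHIIKKLLMMK")
  for (i in 1:20) {
    peps <- replicate(sample(1:6, 1), {
      p <- sample(names(proteins), 1)
      start <- sample(nchar(proteins[[p]]) - 4, 1)
      substr(proteins[[p]], start, start + 3)
    })
    base <- peptide_support(proteins,
                            data.frame(peptide = peps, spectrum_count = 1))
    extra <- peptide_support(proteins,
                             data.frame(peptide = c(peps, "MKTR"),
                                        spectrum_count = 1))
    for (mp in 1:4) {
      c_base <- call_venom_proteins(names(proteins), base, mp)$gene_id
      c_extra <- call_venom_proteins(names(proteins), extra, mp)$gene_id
      expect_true(all(c_base %in% c_extra))
      c_strict <- call_venom_proteins(names(proteins), base, mp + 1)$gene_id
      expect_true(all(c_strict %in% c_base))
    }
  }
})

test_that("call sets nest: highly expressed VPs within VPs within the expressed set", {
  cfg <- small_sim_config(seed = 12)
  sim <- simulate_expression(cfg)
  proteins <- simulate_proteins(cfg, sim$truth)
  peptides <- simulate_peptide_evidence(proteins, sim$truth, cfg)
  vg <- samples_of_tissue(sim$matrix, "venom_gland")
  expressed <- call_expressed(sim$matrix, vg)
  sup <- peptide_support(proteins, peptides)
  venom <- call_venom_proteins(expressed, sup, 3)
  expect_true(all(venom$gene_id %in% expressed$genes))
  if (nrow(venom) >= 3) {
    vg_mean <- rowMeans(sim$matrix$values[, vg, drop = FALSE])
    high <- tryCatch(call_highly_expressed_vps(venom, vg_mean, 0.05),
                     error = function(e) NULL)
    if (!is.null(high)) expect_true(all(high$gene_id %in% venom$gene_id))
  }
})

test_that("functional classification applies keyword priority digestion > ribosome > immunity", {
  ann <- data.frame(
    gene_id = paste0("g", 1:6),
    domain_accessions = "",
    function_text = c("trypsin-like serine protease",
                      "40S ribosomal protein S3",
                      "protease associated with ribosomal assembly",
                      "lysozyme c",
                      "hypothetical protein",
                      "zinc finger protein"),
    stringsAsFactors = FALSE)
  fc <- classify_function(ann)
  expect_identical(fc$class,
                   c("digestion", "ribosome", "digestion", "immunity",
                     "unknown", "other"))
})

test_that("teratocyte effector calling is invariant to sample-column order and degenerates safely", {
  cfg <- small_sim_config(seed = 8)
  sim <- simulate_expression(cfg)
  ann <- simulate_annotation(cfg, sim$truth)
  tc <- samples_of_tissue(sim$matrix, "teratocyte")
  r1 <- call_teratocyte_effectors(sim$matrix, tc, ann)

  perm <- sample(ncol(sim$matrix$values))
  em2 <- expression_matrix(sim$matrix$values[, perm],
                           sim$matrix$metadata[perm, ])
  r2 <- call_teratocyte_effectors(em2, tc, ann)
  expect_setequal(r1$expressed$genes, r2$expressed$genes)
  expect_identical(r1$calls, r2$calls)

  # all-zero teratocyte samples yield zero effectors
  em0 <- sim$matrix
  em0$values[, tc] <- 0
  r0 <- call_teratocyte_effectors(em0, tc, ann)
  expect_equal(nrow(r0$calls), 0)
  expect_error(call_teratocyte_effectors(sim$matrix, "absent.r1", ann),
               "teratocyte sample group")
})

test_that("planted teratocyte digestion genes are recovered in the high subset", {
  recalled <- total <- 0
  for (s in 1:25) {
    cfg <- small_sim_config(seed = 1000 + s)
    sim <- simulate_expression(cfg)
    ann <- simulate_annotation(cfg, sim$truth)
    tc <- samples_of_tissue(sim$matrix, "teratocyte")
    res <- call_teratocyte_effectors(sim$matrix, tc, ann)
    planted <- sim$truth$gene_id[sim$truth$specialized &
                                   sim$truth$focal_tissue == "teratocyte"]
    high <- res$calls$gene_id[res$calls$category == "teratocyte_high"]
    recalled <- recalled + sum(planted %in% high)
    total <- total + length(planted)
    expect_true(all(res$calls$class[res$calls$gene_id %in% planted] ==
                      "digestion"))
  }
  expect_gte(recalled / total, 0.9)
})
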