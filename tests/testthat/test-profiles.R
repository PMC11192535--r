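test_that("N99 threshold matches the cumulative-scan definition on worked examples", {
  expect_equal(compute_n99(c(g1 = 1000)),
               list(threshold = 1000, n_expressed = 1L, fraction = 0.99,
                    expressed_rule = "inclusive_ge"))
  v <- c(g1 = 50, g2 = 30, g3 = 15, g4 = 4, g5 = 1)
  r <- compute_n99(v, 0.99)
  expect_equal(r$threshold, 4)
  expect_equal(r$n_expressed, 4L)
  expect_equal(compute_n99(v, 0.99, "strict_gt")$n_expressed, 3L)
  r2 <- compute_n99(c(g1 = 99, g2 = 1), 0.99)
  expect_equal(r2$threshold, 99)
  expect_equal(r2$n_expressed, 1L)
  # all-zero group: threshold defined as 0 with nothing expressed
  expect_equal(compute_n99(c(a = 0, b = 0))$n_expressed, 0L)
  expect_error(compute_n99(v, 1.2), "fraction")
  expect_error(compute_n99(c(-1, 2)), ">= 0")
})

test_that("compute_n99 equals the naive sort-and-scan oracle on random vectors", {
  set.seed(7)
  for (i in 1:300) {
    n <- sample(1:300, 1)
    v <- round(2^rnorm(n, 3, 2), 3)
    v[sample(n, floor(n * runif(1, 0, 0.5)))] <- 0
    names(v) <- paste0("g", seq_len(n))
    frac <- sample(c(0.9, 0.95, 0.99), 1)
    rule <- sample(c("inclusive_ge", "strict_gt"), 1)
    got <- compute_n99(v, frac, rule)
    want <- naive_n99(v, frac, rule)
    expect_identical(got$threshold, want$threshold)
    expect_identical(got$n_expressed, want$n_expressed)
  }
})

test_that("call_expressed applies the group N99 threshold under both rules", {
  v <- matrix(c(50, 30, 15, 4, 1), 5, 1,
              dimnames = list(paste0("g", 1:5), "vg.r1"))
  em <- expression_matrix(cbind(v, vg.r2 = v[, 1]),
                          data.frame(sample_id = c("vg.r1", "vg.r2"),
                                     tissue = "venom_gland", stage = "adult",
                                     sex = "f", replicate = 1:2))
  expect_setequal(call_expressed(em, c("vg.r1", "vg.r2"))$genes,
                  c("g1", "g2", "g3", "g4"))
  expect_setequal(call_expressed(em, c("vg.r1", "vg.r2"),
                                 expressed_rule = "strict_gt")$genes,
                  c("g1", "g2", "g3"))
  # one gene holding all signal is the only expressed gene
  em1 <- tiny_em(values = matrix(c(100, 0, 0, 0, rep(1, 20)), 4, 6,
                                 dimnames = list(paste0("g", 1:4),
                                                 tiny_em()$metadata$sample_id)))
  expect_identical(call_expressed(em1, "vg.r1")$genes, "g1")
  expect_error(call_expressed(em, "nope.r1"), "unknown sample")
})

test_that("raising a gene's TPM never removes it from the expressed set", {
  set.seed(11)
  for (i in 1:30) {
    em <- tiny_em(n_genes = 30)
    grp <- c("vg.r1", "vg.r2")
    before <- call_expressed(em, grp)$genes
    g <- sample(rownames(em$values), 1)
    em$values[g, grp] <- em$values[g, grp] * runif(1, 1, 20)
    after <- call_expressed(em, grp)$genes
    if (g %in% before) expect_true(g %in% after)
  }
})

test_that("specialization index is the focal mean over the mean of other group means", {
  em <- tiny_em(values = matrix(5, 4, 6,
                                dimnames = list(paste0("g", 1:4),
                                                tiny_em()$metadata$sample_id)))
  si <- specialization_index(em, c("vg.r1", "vg.r2"))
  expect_true(all(si$index == 1))

  # focal mean 10; other groups (teratocyte, whole_body, ovipositor) all mean 2
  m <- matrix(c(10, 10, 2, 2, 2, 2), 1, 6,
              dimnames = list("g1", tiny_em()$metadata$sample_id))
  em2 <- tiny_em(values = m)
  expect_equal(specialization_index(em2, c("vg.r1", "vg.r2"))$index, 5)

  m[1, 1:2] <- 0
  expect_equal(specialization_index(tiny_em(values = m),
                                    c("vg.r1", "vg.r2"))$index, 0)
  m[1, ] <- c(3, 3, 0, 0, 0, 0)
  expect_equal(specialization_index(tiny_em(values = m),
                                    c("vg.r1", "vg.r2"))$index, Inf)
  m[1, ] <- 0
  expect_true(is.nan(specialization_index(tiny_em(values = m),
                                          c("vg.r1", "vg.r2"))$index))
  expect_error(specialization_index(em, c("vg.r1"), genes = "missing"),
               "absent")
})

test_that("replicate-heavy groups do not dominate the specialization denominator", {
  # teratocyte has 2 replicates, ovipositor 1: group means are averaged,
  # not raw samples
  m <- matrix(c(8, 8, 4, 4, 1, 1), 1, 6,
              dimnames = list("g1", tiny_em()$metadata$sample_id))
  si <- specialization_index(tiny_em(values = m), c("vg.r1", "vg.r2"))
  expect_equal(si$other_mean, mean(c(4, 1, 1)))  # not mean(c(4,4,1,1))
})

test_that("high-expression Z test standardizes with the sample sd and the upper normal tail", {
  v <- c(a = 1, b = 1, c = 1, d = 1, e = 6)
  r <- call_high_expression(v, alpha = 0.05, log_transform = FALSE)
  top <- r[r$gene_id == "e", ]
  expect_equal(top$z, 4 / sqrt(5), tolerance = 1e-12)
  expect_equal(top$p, pnorm(4 / sqrt(5), lower.tail = FALSE), tolerance = 1e-12)
  expect_true(top$called)
  expect_false(any(r$called[r$gene_id != "e"]))

  expect_error(call_high_expression(c(2, 2, 2)), "degenerate")
  expect_error(call_high_expression(c(1, 2)), "at least 3")
})

test_that("scale invariance: TPM rescaling preserves indices and scales thresholds", {
  set.seed(5)
  for (i in 1:20) {
    em <- tiny_em(n_genes = 25)
    cc <- 2^sample(c(-3:-1, 1:8), 1)   # dyadic factors make scaling exact
    em2 <- em
    em2$values <- em$values * cc
    s1 <- specialization_index(em, c("vg.r1", "vg.r2"))
    s2 <- specialization_index(em2, c("vg.r1", "vg.r2"))
    expect_identical(s1$index, s2$index)
    t1 <- compute_n99(em$values[, 1])$threshold
    t2 <- compute_n99(em2$values[, 1])$threshold
    expect_identical(t2, t1 * cc)
  }
})

test_that("profile clustering orders by expression-pattern similarity deterministically", {
  m <- rbind(g1 = c(1, 2, 3, 4, 5, 6),
             g2 = c(2, 4, 6, 8, 10, 12),
             g3 = c(6, 5, 4, 3, 2, 1))
  colnames(m) <- tiny_em()$metadata$sample_id
  cl <- cluster_profiles(m)
  # first merge joins the perfectly correlated pair at height 0
  expect_equal(cl$hclust$height[1], 0, tolerance = 1e-12)
  expect_setequal(cl$hclust$labels[-cl$hclust$merge[1, ]], c("g1", "g2"))

  # permuting gene order leaves leaf order unchanged
  cl2 <- cluster_profiles(m[c(3, 1, 2), ])
  expect_identical(cl$order, cl2$order)

  # zero-variance genes group last; single gene is a trivial ordering
  m2 <- rbind(m, g0 = rep(2, 6))
  expect_identical(cluster_profiles(m2)$constant, "g0")
  expect_identical(utils::tail(cluster_profiles(m2)$order, 1), "g0")
  expect_identical(cluster_profiles(m["g1", , drop = FALSE])$order, "g1")
})

test_that("sample ordination matches a direct eigendecomposition oracle", {
  set.seed(9)
  m <- matrix(2^rnorm(30, 4, 1), 10, 3,
              dimnames = list(paste0("g", 1:10), c("s1", "s2", "s3")))
  pr <- project_samples(m)
  x <- log2(m + 1)
  xc <- scale(t(x), center = TRUE, scale = FALSE)  # center genes across samples
  ev <- eigen(stats::cov(xc))
  coords <- xc %*% ev$vectors
  for (k in 1:2) {
    expect_equal(abs(unname(pr$coordinates[, k])), abs(unname(coords[, k])),
                 tolerance = 1e-8)
  }
  expect_equal(pr$var_fraction,
               ev$values[seq_along(pr$var_fraction)] / sum(ev$values),
               tolerance = 1e-8)
  expect_true(all(diff(pr$var_fraction) <= 1e-12))
  expect_lte(sum(pr$var_fraction), 1 + 1e-12)

  # identical samples coincide in projection space
  m2 <- cbind(m, s4 = m[, "s3"])
  pr2 <- project_samples(m2)
  expect_equal(pr2$coordinates["s3", ], pr2$coordinates["s4", ],
               tolerance = 1e-10)
  expect_error(project_samples(m[, 1, drop = FALSE]), "at least 2 samples")
})

test_that("ddCt fold change follows 2^-(dCt_sample - dCt_control)", {
  expect_equal(ddct_fold_change(20, 15, 22, 17), 1)
  expect_equal(ddct_fold_change(22, 20, 26, 20), 16)
  expect_equal(ddct_fold_change(26, 20, 22, 20), 0.0625)
  expect_error(ddct_fold_change(NA, 1, 2, 3), "finite")
})
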