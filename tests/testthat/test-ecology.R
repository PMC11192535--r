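test_that("parasitism and emergence rates follow the printed formulas on the 0-100 scale", {
  expect_equal(parasitism_rate(20, 3), 85)
  expect_equal(parasitism_rate(20, 0), 100)
  expect_equal(parasitism_rate(20, 20), 0)
  expect_equal(emergence_rate(20, 15), 75)
  expect_equal(emergence_rate(20, 0), 0)
  expect_equal(emergence_rate(20, 20), 100)
  expect_error(parasitism_rate(0, 0), "n_hosts")
  expect_error(emergence_rate(20, 21), "count")
})

test_that("oviposition index is the signed egg-count contrast, antisymmetric in its arguments", {
  expect_equal(oviposition_index(10, 10), 0)
  expect_equal(oviposition_index(30, 10), 50)
  expect_equal(oviposition_index(0, 5), -100)
  expect_error(oviposition_index(0, 0), "undefined-index")
  set.seed(3)
  n1 <- rpois(200, 20); nx <- rpois(200, 20)
  keep <- n1 + nx > 0
  expect_equal(oviposition_index(n1[keep], nx[keep]),
               -oviposition_index(nx[keep], n1[keep]))
})

test_that("signed-rank exact p matches hand enumeration on worked examples", {
  r <- signed_rank_test(c(1, 2, 3, 4, 5))
  expect_equal(r$p, 0.0625)
  expect_match(r$method_detail, "exact")
  expect_equal(signed_rank_test(c(-1, 1))$p, 1)
  expect_error(signed_rank_test(c(0, 0, 0)), "no-information")
})

test_that("signed-rank exact p equals the 2^n sign-enumeration oracle", {
  set.seed(41)
  for (i in 1:150) {
    n <- sample(2:10, 1)
    v <- sample(c(-6:-1, 1:6), n, replace = TRUE)  # ties and sign mixes
    if (all(v == 0)) next
    got <- signed_rank_test(v)$p
    expect_equal(got, signed_rank_enum_p(v), tolerance = 1e-12,
                 label = paste(v, collapse = ","))
  }
})

test_that("signed-rank exact p agrees with the reference implementation when untied", {
  set.seed(43)
  for (i in 1:50) {
    n <- sample(5:20, 1)
    v <- round(rnorm(n, 0.3, 1), 4)
    v <- v[v != 0]
    if (anyDuplicated(abs(v))) next
    ours <- signed_rank_test(v)$p
    ref <- suppressWarnings(stats::wilcox.test(v, exact = TRUE)$p.value)
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("signed-rank large-sample approximation tracks the reference normal approximation", {
  set.seed(47)
  v <- round(rnorm(40, 0.2, 1), 2)
  v <- v[v != 0]
  ours <- signed_rank_test(v)$p
  ref <- suppressWarnings(stats::wilcox.test(v, exact = FALSE,
                                             correct = TRUE)$p.value)
  expect_equal(ours, ref, tolerance = 1e-10)
  expect_match(signed_rank_test(v)$method_detail, "normal approximation")
})

test_that("Pratt zero handling ranks zeros but discards their contribution", {
  v <- c(0, 0, 1, 2, -3)
  r <- signed_rank_test(v, zero_policy = "pratt")
  expect_equal(r$n, 3)
  expect_match(r$method_detail, "pratt")
  # zeros take ranks 1.5, 1.5; |1|,|2|,|3| get ranks 3,4,5
  expect_equal(r$statistic, 3 + 4)
})

test_that("Mann-Whitney exact p matches labeling enumeration on worked examples", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 0.1)
  expect_match(r$method_detail, "exact")
  # identical groups are maximally unsurprising
  r2 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_gte(r2$p, 0.95)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Mann-Whitney exact p equals the pairwise-win enumeration oracle", {
  set.seed(53)
  for (i in 1:60) {
    na <- sample(2:8, 1); nb <- sample(2:(16 - na), 1)
    x <- sample(1000, na + nb)   # no ties
    a <- x[seq_len(na)]; b <- x[-seq_len(na)]
    expect_equal(mann_whitney_u(a, b)$p, mw_enum_p(a, b), tolerance = 1e-12)
  }
})

test_that("Mann-Whitney approximation with ties matches the reference implementation", {
  set.seed(59)
  a <- rpois(12, 10); b <- rpois(14, 12)
  ours <- mann_whitney_u(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = TRUE)$p.value)
  expect_equal(ours$p, ref, tolerance = 1e-10)
  expect_match(ours$method_detail, "ties: TRUE")
})

test_that("Mann-Whitney power increases with location shift", {
  set.seed(61)
  rej <- vapply(c(0, 1, 2), function(shift) {
    mean(vapply(1:300, function(i) {
      a <- rnorm(8); b <- rnorm(8) + shift
      mann_whitney_u(a, b)$p < 0.05
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(rej) > 0))
})

test_that("condition summaries report replicate-mean rates with sample-sd SEM", {
  rec <- data.frame(replicate = 1:3, host_species = "h", host_age_days = 1,
                    mode = "mono", n_hosts = 20,
                    n_emerged_host_adults = c(4, 3, 2),
                    n_emerged_wasps = c(10, 12, 14))
  s <- summarize_conditions(rec)
  expect_equal(s$mean_parasitism_rate, 85)
  expect_equal(s$sem_parasitism_rate, 5 / sqrt(3), tolerance = 1e-12)
  # single replicate: SEM undefined
  s1 <- summarize_conditions(rec[1, ])
  expect_true(is.na(s1$sem_parasitism_rate))
  # record order does not matter
  expect_equal(summarize_conditions(rec[c(3, 1, 2), ]), s)
})

test_that("fold recovery is the ratio of replicate-mean rates", {
  mk <- function(mode, pr, er) data.frame(
    host_species = "h", host_age_days = 4, mode = mode, n_replicates = 6,
    mean_parasitism_rate = pr, sem_parasitism_rate = 1,
    mean_emergence_rate = er, sem_emergence_rate = 1)
  f <- fold_recovery(mk("mono", 20, 20), mk("super", 44, 64))
  expect_equal(f$parasitism_fold, 2.2)
  expect_equal(f$emergence_fold, 3.2)
  f1 <- fold_recovery(mk("mono", 30, 20), mk("super", 30, 20))
  expect_equal(f1$parasitism_fold, 1)
  f0 <- fold_recovery(mk("mono", 30, 20), mk("super", 0, 0))
  expect_equal(f0$parasitism_fold, 0)
  expect_error(fold_recovery(mk("mono", 0, 0), mk("super", 30, 20)),
               "undefined-fold")
})

test_that("choice summaries exclude uninformative zero-egg replicates with a warning", {
  rec <- data.frame(replicate = 1:4, age_x = 4, n1 = c(10, 0, 5, 12),
                    nx = c(5, 0, 10, 3), duration_h = 2)
  expect_warning(out <- summarize_choice(rec), "excluded")
  expect_equal(nrow(out$per_replicate), 3)
  expect_equal(out$summary$n_replicates, 3)
  expect_true(is.finite(out$summary$signed_rank_p))
})

test_that("dissection summaries compare NH and PH oviposition rates by Mann-Whitney", {
  rec <- data.frame(replicate = rep(1:5, 2), group = rep(c("NH", "PH"), each = 5),
                    n_dissected = 20,
                    n_with_eggs = c(17, 18, 16, 19, 17, 3, 2, 4, 1, 3))
  out <- summarize_dissection(rec)
  expect_equal(out$summary$mean_rate[out$summary$group == "NH"], 87)
  expect_lt(out$test$p, 0.05)
  expect_equal(out$test$test, "Mann-Whitney U")
})
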