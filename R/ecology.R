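#' Parasitism and wasp emergence rates
#'
#' Parasitism rate = (1 - emerged host adults / total hosts) x 100;
#' wasp emergence rate = (emerged wasps / total hosts) x 100. Both are
#' returned on the 0-100 scale.
#'
#' @param n_hosts Total hosts exposed (> 0).
#' @param n_emerged_host_adults Host adults that eclosed (escaped
#'   parasitism).
#' @param n_emerged_wasps Wasps that emerged.
#' @return Numeric percentage(s).
#' @export
parasitism_rate <- function(n_hosts, n_emerged_host_adults) {
  check_rate_counts(n_hosts, n_emerged_host_adults)
  (1 - n_emerged_host_adults / n_hosts) * 100
}

#' @rdname parasitism_rate
#' @export
emergence_rate <- function(n_hosts, n_emerged_wasps) {
  check_rate_counts(n_hosts, n_emerged_wasps)
  n_emerged_wasps / n_hosts * 100
}

check_rate_counts <- function(n_hosts, count) {
  if (any(n_hosts == 0))
    stop("input error: n_hosts must be > 0", call. = FALSE)
  if (any(count < 0 | count > n_hosts))
    stop("input error: count must lie in [0, n_hosts]", call. = FALSE)
  invisible(NULL)
}

#' Oviposition preference index
#'
#' (N1 - Nx) / (N1 + Nx) x 100, on the -100..100 scale: positive values
#' mean preference for the 1-day-old (left) side. A replicate with zero
#' eggs on both sides carries no preference information and is an error
#' here; [summarize_choice()] excludes such replicates with a warning.
#'
#' @param n1 Total eggs in 1-day-old (left-side) hosts.
#' @param nx Total eggs in X-day-old (right-side) hosts.
#' @return Numeric index (vectorized).
#' @export
oviposition_index <- function(n1, nx) {
  if (any(n1 < 0 | nx < 0))
    stop("input error: egg counts must be >= 0", call. = FALSE)
  if (any(n1 + nx == 0))
    stop("undefined-index error: N1 + Nx = 0 (no eggs laid)", call. = FALSE)
  (n1 - nx) / (n1 + nx) * 100
}

# Exact null distribution of the signed-rank statistic over doubled
# midranks: counts[w + 1] = number of sign assignments with W+ = w/2.
signed_rank_exact_counts <- function(doubled_ranks) {
  total <- sum(doubled_ranks)
  f <- numeric(total + 1)
  f[1] <- 1
  for (d in doubled_ranks) {
    g <- f
    g[(d + 1):(total + 1)] <- g[(d + 1):(total + 1)] + f[1:(total + 1 - d)]
    f <- g
  }
  f
}

#' Wilcoxon signed-rank test against a location
#'
#' Two-sided one-sample test of symmetry about `mu`. Zeros (values equal
#' to `mu`) are dropped before ranking under the default Wilcoxon
#' convention, or retained for ranking and then discarded under Pratt's
#' method; ties in |value - mu| receive midranks. The p-value is exact —
#' the full null distribution of the signed-rank statistic over all 2^n
#' sign assignments — when n <= `exact_limit`, and a normal approximation
#' with tie correction and continuity correction otherwise. The method
#' actually used is recorded in the result.
#'
#' @param values Numeric observations.
#' @param mu Hypothesized center (default 0).
#' @param zero_policy `"wilcoxon"` (drop zeros, default) or `"pratt"`.
#' @param exact_limit Largest n for which the exact distribution is used
#'   (default 25).
#' @return An object of class `ecology_test`: list with `test`,
#'   `statistic` (W+, rank sum of positive differences), `p`, `n`
#'   (nonzero differences used), `method_detail`.
#' @export
signed_rank_test <- function(values, mu = 0,
                             zero_policy = c("wilcoxon", "pratt"),
                             exact_limit = 25) {
  zero_policy <- match.arg(zero_policy)
  d <- values - mu
  if (all(d == 0))
    stop("no-information error: all values equal mu", call. = FALSE)
  if (zero_policy == "wilcoxon") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    keep <- d != 0
    r <- r_all[keep]
    d <- d[keep]
  }
  n <- length(d)
  w <- sum(r[d > 0])
  dbl <- as.integer(round(2 * r))
  if (n <= exact_limit) {
    counts <- signed_rank_exact_counts(dbl)
    total <- 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(counts[seq_len(w2 + 1)]) / total
    p_ge <- sum(counts[(w2 + 1):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    detail <- sprintf("exact (full sign enumeration, n = %d); zeros: %s; midranks for ties",
                      n, zero_policy)
  } else {
    mu_w <- sum(r) / 2
    sd_w <- sqrt(sum(r^2) / 4)   # tie-corrected: Var(W+) = sum(r_i^2)/4
    z <- if (w > mu_w) (w - mu_w - 0.5) / sd_w
         else if (w < mu_w) (w - mu_w + 0.5) / sd_w
         else 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    detail <- sprintf("normal approximation with tie and continuity correction (n = %d); zeros: %s",
                      n, zero_policy)
  }
  structure(list(test = "Wilcoxon signed rank", statistic = w, p = p, n = n,
                 method_detail = detail), class = "ecology_test")
}

#' Mann-Whitney U test
#'
#' Two-sided two-sample rank test. The p-value is exact — enumeration of
#' all choose(nA + nB, nA) group labelings — when nA + nB <= 16 and no
#' ties are present, and a normal approximation with tie correction and
#' continuity correction otherwise.
#'
#' @param group_a,group_b Numeric observations (both non-empty).
#' @return An object of class `ecology_test` with the U statistic of group
#'   A, `p`, `n` (c(nA, nB)) and `method_detail`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na == 0 || nb == 0)
    stop("input error: both groups must be non-empty", call. = FALSE)
  comb <- c(group_a, group_b)
  r <- rank(comb)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  nn <- na + nb
  has_ties <- anyDuplicated(comb) > 0
  if (nn <= 16 && !has_ties) {
    sets <- utils::combn(nn, na)
    ranks <- sort(r)                      # 1..N, no ties
    u_all <- colSums(matrix(ranks[sets], nrow = na)) - na * (na + 1) / 2
    p_le <- mean(u_all <= u)
    p_ge <- mean(u_all >= u)
    p <- min(1, 2 * min(p_le, p_ge))
    detail <- sprintf("exact (labeling enumeration, %d of %d+%d)", ncol(sets), na, nb)
  } else {
    mu_u <- na * nb / 2
    ties <- table(comb)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    var_u <- na * nb / 12 * ((nn + 1) - tie_term)
    z <- if (u > mu_u) (u - mu_u - 0.5) / sqrt(var_u)
         else if (u < mu_u) (u - mu_u + 0.5) / sqrt(var_u)
         else 0
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    detail <- sprintf("normal approximation with tie and continuity correction (nA = %d, nB = %d, ties: %s)",
                      na, nb, has_ties)
  }
  structure(list(test = "Mann-Whitney U", statistic = u, p = p, n = c(na, nb),
                 method_detail = detail), class = "ecology_test")
}

#' @export
print.ecology_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %g, p = %g [%s]\n",
              x$test, x$statistic, x$p, x$method_detail))
  invisible(x)
}

#' Summarize parasitism assay replicates by condition
#'
#' Per (host species, host age, parasitism mode) condition: replicate-level
#' parasitism and emergence rates, their means and SEMs (sample sd / sqrt
#' n; undefined for a single replicate). Conditions are ordered by key so
#' output is independent of record order.
#'
#' @param records Data frame of parasitism records (see
#'   [read_assay_records()]).
#' @return Data frame, one row per condition: `host_species`,
#'   `host_age_days`, `mode`, `n_replicates`, `mean_parasitism_rate`,
#'   `sem_parasitism_rate`, `mean_emergence_rate`, `sem_emergence_rate`.
#' @export
summarize_conditions <- function(records) {
  if (nrow(records) == 0)
    stop("input error: no records", call. = FALSE)
  key <- with(records, paste(host_species, host_age_days, mode, sep = "|"))
  out <- lapply(sort(unique(key)), function(k) {
    rec <- records[key == k, , drop = FALSE]
    pr <- parasitism_rate(rec$n_hosts, rec$n_emerged_host_adults)
    er <- emergence_rate(rec$n_hosts, rec$n_emerged_wasps)
    sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
    data.frame(host_species = rec$host_species[1],
               host_age_days = rec$host_age_days[1],
               mode = rec$mode[1], n_replicates = nrow(rec),
               mean_parasitism_rate = mean(pr), sem_parasitism_rate = sem(pr),
               mean_emergence_rate = mean(er), sem_emergence_rate = sem(er),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Fold recovery of parasitic efficiency by superparasitism
#'
#' Ratio of the superparasitism condition's mean rate to the
#' monoparasitism condition's mean rate, computed on replicate-mean rates
#' (matching the mean +/- SEM presentation of replicate-level assays), for
#' both the parasitism and the emergence rate.
#'
#' @param summary_mono,summary_super Single-condition rows from
#'   [summarize_conditions()] for the same host species and age.
#' @return List with `parasitism_fold` and `emergence_fold`.
#' @export
fold_recovery <- function(summary_mono, summary_super) {
  if (nrow(summary_mono) != 1 || nrow(summary_super) != 1)
    stop("input error: expected exactly one condition row per mode", call. = FALSE)
  if (summary_mono$host_species != summary_super$host_species ||
      summary_mono$host_age_days != summary_super$host_age_days)
    stop("input error: mono and super summaries must share host species and age",
         call. = FALSE)
  if (summary_mono$mean_parasitism_rate == 0 ||
      summary_mono$mean_emergence_rate == 0)
    stop("undefined-fold error: monoparasitism mean rate is zero", call. = FALSE)
  list(parasitism_fold = summary_super$mean_parasitism_rate /
         summary_mono$mean_parasitism_rate,
       emergence_fold = summary_super$mean_emergence_rate /
         summary_mono$mean_emergence_rate)
}

#' Summarize two-choice oviposition assays
#'
#' Computes the oviposition index per replicate (replicates with zero eggs
#' on both sides are excluded with a warning: they carry no preference
#' information), then per (age_x, duration) condition the mean index, SEM
#' and a Wilcoxon signed-rank test of deviation from zero.
#'
#' @param records Choice records (see [read_assay_records()]).
#' @param zero_policy Passed to [signed_rank_test()].
#' @return List with `per_replicate` (records + `index`) and `summary`
#'   (one row per condition with `mean_index`, `sem_index`,
#'   `signed_rank_p`, `method_detail`).
#' @export
summarize_choice <- function(records, zero_policy = "wilcoxon") {
  empty <- records$n1 + records$nx == 0
  if (any(empty)) {
    warning(sum(empty), " choice replicate(s) with no eggs excluded")
    records <- records[!empty, , drop = FALSE]
  }
  if (nrow(records) == 0)
    stop("input error: no informative choice replicates", call. = FALSE)
  records$index <- oviposition_index(records$n1, records$nx)
  key <- with(records, paste(age_x, duration_h, sep = "|"))
  out <- lapply(sort(unique(key)), function(k) {
    rec <- records[key == k, , drop = FALSE]
    idx <- rec$index
    tst <- if (any(idx != 0))
      signed_rank_test(idx, mu = 0, zero_policy = zero_policy)
    else list(p = NA_real_, method_detail = "all indices zero; no test")
    data.frame(age_x = rec$age_x[1], duration_h = rec$duration_h[1],
               n_replicates = nrow(rec), mean_index = mean(idx),
               sem_index = if (nrow(rec) > 1) stats::sd(idx) / sqrt(nrow(rec)) else NA_real_,
               signed_rank_p = tst$p, method_detail = tst$method_detail,
               stringsAsFactors = FALSE)
  })
  list(per_replicate = records, summary = do.call(rbind, out))
}

#' Summarize interspecific-competition dissection assays
#'
#' Per-replicate oviposition rate (% of dissected hosts containing eggs)
#' for the parasitized-host (PH) and non-parasitized-host (NH) groups,
#' with a Mann-Whitney U test between groups.
#'
#' @param records Dissection records (see [read_assay_records()]).
#' @return List with `per_replicate`, `summary` (mean/SEM per group) and
#'   `test` (the [mann_whitney_u()] result, or `NULL` if a group is
#'   missing).
#' @export
summarize_dissection <- function(records) {
  records$oviposition_rate <- records$n_with_eggs / records$n_dissected * 100
  out <- lapply(sort(unique(records$group)), function(g) {
    r <- records$oviposition_rate[records$group == g]
    data.frame(group = g, n_replicates = length(r), mean_rate = mean(r),
               sem_rate = if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  tst <- NULL
  if (all(c("NH", "PH") %in% records$group))
    tst <- mann_whitney_u(records$oviposition_rate[records$group == "NH"],
                          records$oviposition_rate[records$group == "PH"])
  list(per_replicate = records, summary = do.call(rbind, out), test = tst)
}
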