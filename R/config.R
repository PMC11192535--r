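#' Pipeline run configuration
#'
#' Bundles the fixed analysis constants used across all pipeline stages:
#' the cumulative-abundance fraction for the N99 expression threshold, the
#' minimum number of distinct proteomic peptides required to call a venom
#' protein, the significance level of the high-expression Z test, the
#' expressed-rule boundary, and the keyword taxonomy used to classify
#' effector function.
#'
#' @param seed Integer master seed; reproduces identical outputs end-to-end.
#' @param n99_fraction Cumulative fraction of total transcript abundance that
#'   defines the expression threshold (default 0.99, i.e. N99).
#' @param min_peptides Minimum distinct matched peptides for a venom-protein
#'   call (default 3).
#' @param alpha Significance level for the high-expression Z test
#'   (default 0.05).
#' @param expressed_rule Boundary rule at the N99 threshold:
#'   `"inclusive_ge"` counts the threshold-defining gene itself as expressed
#'   (default), `"strict_gt"` requires TPM strictly above the threshold.
#' @param il_equivalence Treat isoleucine and leucine as interchangeable in
#'   peptide-to-protein matching (default `FALSE`).
#' @param digestion_keywords Lowercase keywords defining the digestion
#'   functional class; see [default_function_keywords()].
#' @param pseudocount Optional pseudocount added to numerator and denominator
#'   of the specialization index (default 0: ratios of 0 and +Inf are kept).
#' @param vg_tissue,teratocyte_tissue Tissue labels (in the sample metadata)
#'   of the venom-gland and teratocyte groups.
#' @param outlier_cutoff Robust-z cutoff above which a domain expansion is
#'   flagged as an outlier (default 5).
#'
#' @return An object of class `run_config` (a validated list).
#' @export
run_config <- function(seed = 1L,
                       n99_fraction = 0.99,
                       min_peptides = 3L,
                       alpha = 0.05,
                       expressed_rule = c("inclusive_ge", "strict_gt"),
                       il_equivalence = FALSE,
                       digestion_keywords = default_function_keywords()$digestion,
                       pseudocount = 0,
                       vg_tissue = "venom_gland",
                       teratocyte_tissue = "teratocyte",
                       outlier_cutoff = 5) {
  expressed_rule <- match.arg(expressed_rule)
  cfg <- list(
    seed = as.integer(seed),
    n99_fraction = n99_fraction,
    min_peptides = as.integer(min_peptides),
    alpha = alpha,
    expressed_rule = expressed_rule,
    il_equivalence = isTRUE(il_equivalence),
    digestion_keywords = tolower(digestion_keywords),
    pseudocount = pseudocount,
    vg_tissue = vg_tissue,
    teratocyte_tissue = teratocyte_tissue,
    outlier_cutoff = outlier_cutoff
  )
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.finite(cfg$n99_fraction) || cfg$n99_fraction <= 0 || cfg$n99_fraction >= 1)
    stop("config error: n99_fraction must lie strictly between 0 and 1, got ",
         cfg$n99_fraction, call. = FALSE)
  if (is.na(cfg$min_peptides) || cfg$min_peptides < 1L)
    stop("config error: min_peptides must be an integer >= 1", call. = FALSE)
  if (!is.finite(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("config error: alpha must lie strictly between 0 and 1", call. = FALSE)
  if (is.na(cfg$seed))
    stop("config error: seed must be a finite integer", call. = FALSE)
  if (cfg$pseudocount < 0)
    stop("config error: pseudocount must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' @export
print.run_config <- function(x, ...) {
  cat("effector-screen run configuration\n")
  cat(sprintf("  seed: %d, N%g threshold, expressed rule: %s\n",
              x$seed, 100 * x$n99_fraction, x$expressed_rule))
  cat(sprintf("  venom call: >= %d distinct peptides; Z test alpha = %g\n",
              x$min_peptides, x$alpha))
  cat(sprintf("  I/L equivalence: %s; specialization pseudocount: %g\n",
              x$il_equivalence, x$pseudocount))
  invisible(x)
}

#' Default keyword taxonomy for functional classification
#'
#' Lowercase substrings matched against free-text functional annotation to
#' assign the classes used in the teratocyte-effector screen. Class priority
#' when several keywords match is digestion > ribosome > immunity. The lists
#' are editable: the category labels in the literature ("digestion-related",
#' "ribosome-related") are not defined by an enumerated vocabulary, so the
#' taxonomy ships as data a user can extend.
#'
#' @return Named list of character vectors (`digestion`, `ribosome`,
#'   `immunity`).
#' @export
default_function_keywords <- function() {
  list(
    digestion = c("trypsin", "chymotrypsin", "serine protease", "protease",
                  "proteinase", "peptidase", "lipase", "amylase",
                  "glucosidase", "chitinase", "esterase", "carboxypeptidase",
                  "digestive"),
    ribosome = c("ribosom", "60s ", "40s ", "elongation factor",
                 "translation initiation"),
    immunity = c("immun", "antimicrobial", "defensin", "lysozyme", "serpin",
                 "peptidoglycan recognition", "c-type lectin", "toll")
  )
}

# Derive per-stream sub-seeds from a master seed so that, e.g., changing the
# assay design never perturbs the expression draw. Kept below 2^31 - 1.
derive_seeds <- function(master, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}
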