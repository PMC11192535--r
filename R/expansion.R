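#' Build a species x domain gene-copy count table
#'
#' Counts, per species and domain accession, the number of distinct genes
#' carrying that domain. A gene listing the same domain twice contributes
#' one copy; missing (species, domain) pairs are zero.
#'
#' @param annotations Data frame with columns `species`, `gene`, `domain`.
#' @return Integer matrix, species in rows, domain accessions in columns.
#' @export
count_domains <- function(annotations) {
  need <- c("species", "gene", "domain")
  miss <- setdiff(need, names(annotations))
  if (length(miss))
    stop("input error: annotation rows need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  bad <- !grepl("^[A-Za-z0-9][A-Za-z0-9_.:-]*$", annotations$domain)
  if (any(bad))
    stop("input error: malformed domain accession: '",
         annotations$domain[which(bad)[1]], "'", call. = FALSE)
  u <- unique(annotations[, need])
  species <- sort(unique(u$species))
  domains <- sort(unique(u$domain))
  m <- matrix(0L, length(species), length(domains),
              dimnames = list(species, domains))
  tab <- table(factor(u$species, species), factor(u$domain, domains))
  m[] <- as.integer(tab)
  m
}

#' Rank gene-family domain expansions of a focal species
#'
#' For each domain, the expansion score is the focal species' gene-copy
#' count minus the maximum count among comparator species ("much more than
#' any other species" compares against the best comparator, and the maximum
#' is robust to comparator-set composition). Domains are ranked by score
#' descending, ties broken by the shrunken ratio
#' (focal + 1)/(max_other + 1) descending, then accession ascending, so the
#' ranking is total and deterministic. Domains absent from the focal
#' species are retained with score <= 0 (contractions stay visible).
#'
#' @param counts Species x domain integer matrix (see [count_domains()] or
#'   [read_domain_counts()]).
#' @param focal_species Row name of the focal species.
#' @return Data frame with `domain`, `focal_count`, `max_other`, `score`,
#'   `ratio`, `rank`, ordered by rank.
#' @export
rank_expansions <- function(counts, focal_species) {
  if (nrow(counts) < 2)
    stop("input error: need at least 2 species", call. = FALSE)
  if (!focal_species %in% rownames(counts))
    stop("input error: focal species '", focal_species,
         "' absent from count table", call. = FALSE)
  focal <- counts[focal_species, ]
  others <- counts[setdiff(rownames(counts), focal_species), , drop = FALSE]
  max_other <- apply(others, 2, max)
  score <- focal - max_other
  ratio <- (focal + 1) / (max_other + 1)
  ord <- order(-score, -ratio, colnames(counts))
  out <- data.frame(domain = colnames(counts)[ord],
                    focal_count = as.integer(focal[ord]),
                    max_other = as.integer(max_other[ord]),
                    score = as.numeric(score[ord]),
                    ratio = as.numeric(ratio[ord]),
                    rank = seq_len(ncol(counts)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Flag extreme expansion outliers by robust z
#'
#' Standardizes expansion scores with the median and the scaled median
#' absolute deviation, robust_z = (score - median) / (1.4826 * MAD); a
#' domain is an outlier when robust_z exceeds `cutoff`. Expansion-score
#' distributions are heavy-tailed by construction, hence median/MAD rather
#' than mean/sd. When the MAD is zero (more than half the scores equal the
#' median) the dispersion falls back to the mean absolute deviation about
#' the median; if that is also zero no outlier exists.
#'
#' @param results Data frame from [rank_expansions()] (>= 5 domains).
#' @param cutoff Robust-z cutoff (default 5, conservative).
#' @return `results` with `robust_z` and `outlier` columns appended;
#'   attribute `dispersion_method` records which estimate was used.
#' @export
flag_outliers <- function(results, cutoff = 5) {
  if (nrow(results) < 5)
    stop("input error: need at least 5 domains to flag outliers", call. = FALSE)
  s <- results$score
  med <- stats::median(s)
  disp <- stats::mad(s)            # 1.4826 * median(|s - med|)
  method <- "1.4826*MAD"
  if (disp == 0) {
    disp <- mean(abs(s - med))
    method <- "mean absolute deviation (MAD fallback)"
  }
  if (disp == 0) {
    results$robust_z <- 0
    results$outlier <- FALSE
    method <- "no dispersion; no outliers"
  } else {
    results$robust_z <- (s - med) / disp
    results$outlier <- results$robust_z > cutoff
  }
  attr(results, "dispersion_method") <- method
  results
}
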