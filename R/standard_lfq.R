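#' Kruskal-Wallis rank test across condition groups
#'
#' Thin wrapper over [stats::kruskal.test()] returning the tie-corrected H
#' statistic and its chi-square p-value with `k - 1` degrees of freedom.
#' When every observation is identical there is no rank information: H is 0
#' and p is 1 (the base test returns NaN in that fully tied case).
#'
#' @param groups list of numeric vectors, one per group (>= 2 groups, each
#'   non-empty).
#' @return a list with `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) == 0))
    stop("every group must be non-empty", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1) return(list(H = 0, p = 1))
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  res <- stats::kruskal.test(x, g)
  list(H = unname(res$statistic), p = res$p.value)
}

#' Conventional LFQ protein selection
#'
#' The cross-validating comparator to the peptide-based strategy: a peptide
#' qualifies when it is (i) detected (observed pre-imputation) in at least
#' `min_detected_A` condition-A runs, (ii) at least `fold_min`-fold more
#' intense on average in A than in B (zero-imputed means, inclusive
#' threshold), and (iii) significantly different between conditions by the
#' Kruskal-Wallis test at level `alpha` (zero-imputed intensities, so
#' missing B values count as zeros rather than excluding runs). A protein
#' group is selected when it has at least `min_qualifying` qualifying
#' peptides.
#'
#' @param table a `peptide_table` (imputed or not; the pre-imputation
#'   detection mask is used for the detection filter).
#' @param min_detected_A minimum number of A runs with an observed intensity.
#' @param fold_min minimum A:B mean-intensity ratio.
#' @param alpha significance level of the Kruskal-Wallis filter (per peptide,
#'   uncorrected).
#' @param min_qualifying qualifying peptides required per protein group.
#' @return a list with `proteins` (character vector of selected protein
#'   groups) and `peptides` (data.frame of per-peptide filter outcomes).
#' @export
standard_lfq_select <- function(table, min_detected_A = 10, fold_min = 1.3,
                                alpha = 0.05, min_qualifying = 1) {
  stopifnot(inherits(table, "peptide_table"))
  if (min_detected_A < 1) stop("min_detected_A must be >= 1", call. = FALSE)
  if (fold_min <= 1) stop("fold_min must be > 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  detected <- detection_mask(table)
  if (!isTRUE(attr(table, "imputed"))) table <- impute_missing_as_zero(table)
  a_runs <- table$design$condition == "A"
  b_runs <- table$design$condition == "B"
  n_det_a <- rowSums(detected[, a_runs, drop = FALSE])
  mean_a <- rowMeans(table$intensities[, a_runs, drop = FALSE])
  mean_b <- rowMeans(table$intensities[, b_runs, drop = FALSE])
  fold_ok <- mean_a >= fold_min * mean_b
  det_ok <- n_det_a >= min_detected_A
  p_kw <- rep(NA_real_, nrow(table$intensities))
  # only peptides passing the cheap filters need the rank test
  for (i in which(det_ok & fold_ok)) {
    p_kw[i] <- kruskal_wallis(list(table$intensities[i, a_runs],
                                   table$intensities[i, b_runs]))$p
  }
  qualifies <- det_ok & fold_ok & !is.na(p_kw) & p_kw < alpha
  peptides <- data.frame(peptide_id = rownames(table$intensities),
                         protein_group = table$peptides$protein_group,
                         n_detected_A = n_det_a,
                         mean_A = mean_a, mean_B = mean_b,
                         p_kw = p_kw, qualifies = qualifies,
                         stringsAsFactors = FALSE, row.names = NULL)
  n_qual <- tapply(qualifies, table$peptides$protein_group, sum)
  proteins <- names(n_qual)[n_qual >= min_qualifying]
  list(proteins = sort(proteins), peptides = peptides)
}

#' Concordance between two protein selections
#'
#' Percentage of the peptide-based calls that the comparator strategy also
#' selected: `100 * |peptide_based intersect standard| / |peptide_based|`.
#'
#' @param peptide_based character vector of protein groups from the
#'   peptide-based strategy (non-empty).
#' @param standard character vector from the comparator strategy.
#' @return percentage in \[0, 100\].
#' @export
concordance <- function(peptide_based, standard) {
  peptide_based <- unique(peptide_based)
  if (!length(peptide_based))
    stop("concordance undefined for an empty peptide-based set",
         call. = FALSE)
  100 * length(intersect(peptide_based, standard)) / length(peptide_based)
}
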