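#' One-way random-effects intraclass correlation
#'
#' ICC(1) from a one-way ANOVA decomposition:
#' `(MSB - MSW) / (MSB + (k0 - 1) * MSW)` where `MSB` and `MSW` are the
#' between- and within-class mean squares and `k0` is the effective class
#' size (`(N - sum(n_i^2) / N) / (a - 1)`, equal to the common class size for
#' balanced designs). Negative estimates are clamped to 0. A table whose
#' values are all identical has no variance to partition and returns 1, the
#' continuity limit of perfect repeatability.
#'
#' @param values numeric vector of observations.
#' @param classes grouping factor (coerced) of the same length, e.g. the
#'   biological replicate of each run.
#' @return the ICC, a number in \[0,1\].
#' @export
icc_oneway <- function(values, classes) {
  if (length(values) != length(classes))
    stop("`values` and `classes` must have the same length", call. = FALSE)
  keep <- !is.na(values)
  values <- values[keep]
  classes <- factor(classes[keep])
  n_i <- tabulate(classes)
  a <- nlevels(classes)
  N <- length(values)
  if (a < 2 || N < 2 || N <= a)
    stop("ICC undefined: need >= 2 classes and replicate observations",
         call. = FALSE)
  grand <- mean(values)
  class_means <- tapply(values, classes, mean)
  ssb <- sum(n_i * (class_means - grand)^2)
  ssw <- sum((values - class_means[classes])^2)
  msb <- ssb / (a - 1)
  msw <- ssw / (N - a)
  if (msw == 0) return(1)  # no within-class noise: perfect repeatability
  k0 <- (N - sum(n_i^2) / N) / (a - 1)
  icc <- (msb - msw) / (msb + (k0 - 1) * msw)
  max(0, icc)
}

#' Repeatability index of one peptide
#'
#' The detection-reproducibility coordinate of the peptide scoring plane:
#' the one-way ICC of the peptide's condition-A intensities grouped by
#' biological replicate, multiplied by the ICC of the same intensities
#' grouped by preparation (biological x experimental replicate). Condition A
#' carries the target signal, so repeatability is assessed there; set
#' `conditions = c("A", "B")` to include background runs.
#'
#' @param table an imputed `peptide_table` (see [impute_missing_as_zero()]).
#' @param peptide_id the peptide to score.
#' @param conditions which conditions enter the ICC (default `"A"`).
#' @return a list with `icc_bio`, `icc_tech` and their product `r`.
#' @export
repeatability_index <- function(table, peptide_id, conditions = "A") {
  stopifnot(inherits(table, "peptide_table"))
  if (!peptide_id %in% rownames(table$intensities))
    stop("unknown peptide: ", peptide_id, call. = FALSE)
  sel <- table$design$condition %in% conditions
  x <- table$intensities[peptide_id, sel]
  d <- table$design[sel, ]
  icc_bio <- tryCatch(icc_oneway(x, d$bio_rep), error = function(e)
    stop("ICC undefined for peptide ", peptide_id, ": ",
         conditionMessage(e), call. = FALSE))
  icc_tech <- tryCatch(icc_oneway(x, d$prep), error = function(e)
    stop("ICC undefined for peptide ", peptide_id, ": ",
         conditionMessage(e), call. = FALSE))
  list(icc_bio = icc_bio, icc_tech = icc_tech, r = icc_bio * icc_tech)
}

#' Condition-enrichment statistic of one peptide
#'
#' `e = (mean_A - mean_B) / max(mean_A, mean_B)`, computed on zero-imputed
#' intensities so that absence in B counts as zero signal. The statistic is
#' bounded in \[-1, 1\]: `e = 1` for peptides found only in A, `e = 0` for
#' peptides equally abundant in both conditions (and for the 0/0 case of a
#' peptide absent everywhere), `e = -1` for peptides found only in B.
#'
#' @param table an imputed `peptide_table`.
#' @param peptide_id the peptide to score.
#' @return a list with `e`, `mean_A`, `mean_B`.
#' @export
enrichment_score <- function(table, peptide_id) {
  stopifnot(inherits(table, "peptide_table"))
  if (!peptide_id %in% rownames(table$intensities))
    stop("unknown peptide: ", peptide_id, call. = FALSE)
  x <- table$intensities[peptide_id, ]
  x[is.na(x)] <- 0
  mean_a <- mean(x[table$design$condition == "A"])
  mean_b <- mean(x[table$design$condition == "B"])
  denom <- max(mean_a, mean_b)
  e <- if (denom == 0) 0 else (mean_a - mean_b) / denom
  list(e = e, mean_A = mean_a, mean_B = mean_b)
}

#' Score every peptide of a table
#'
#' Computes, for each peptide, the repeatability index
#' ([repeatability_index()]) and the enrichment statistic
#' ([enrichment_score()]); the two coordinates in which peptides are later
#' clustered. Missing values are collapsed to zero first if the table has
#' not been imputed yet. Peptides whose ICC is undefined under the design
#' receive `r = 0` and are flagged in the `degenerate` column.
#'
#' @param table a `peptide_table`.
#' @param conditions conditions used for the repeatability ICCs.
#' @return a `peptide_scores` data.frame with columns `peptide_id`,
#'   `protein_group`, `icc_bio`, `icc_tech`, `repeatability`, `enrichment`,
#'   `mean_A`, `mean_B`, `degenerate`.
#' @export
score_all_peptides <- function(table, conditions = "A") {
  stopifnot(inherits(table, "peptide_table"))
  if (!isTRUE(attr(table, "imputed"))) table <- impute_missing_as_zero(table)
  n <- nrow(table$intensities)
  if (n == 0) {
    warning("empty peptide table: no scores computed")
    out <- data.frame(peptide_id = character(), protein_group = character(),
                      icc_bio = numeric(), icc_tech = numeric(),
                      repeatability = numeric(), enrichment = numeric(),
                      mean_A = numeric(), mean_B = numeric(),
                      degenerate = logical(), stringsAsFactors = FALSE)
    class(out) <- c("peptide_scores", "data.frame")
    return(out)
  }
  sel <- table$design$condition %in% conditions
  d <- table$design[sel, ]
  cond_a <- table$design$condition == "A"
  cond_b <- table$design$condition == "B"
  icc_bio <- icc_tech <- numeric(n)
  degenerate <- logical(n)
  for (i in seq_len(n)) {
    x <- table$intensities[i, sel]
    ok <- tryCatch({
      icc_bio[i] <- icc_oneway(x, d$bio_rep)
      icc_tech[i] <- icc_oneway(x, d$prep)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      icc_bio[i] <- icc_tech[i] <- 0
      degenerate[i] <- TRUE
    }
  }
  mean_a <- rowMeans(table$intensities[, cond_a, drop = FALSE])
  mean_b <- rowMeans(table$intensities[, cond_b, drop = FALSE])
  denom <- pmax(mean_a, mean_b)
  e <- ifelse(denom == 0, 0, (mean_a - mean_b) / denom)
  if (any(degenerate))
    message(sum(degenerate),
            " peptide(s) had an undefined ICC and were scored r = 0")
  out <- data.frame(peptide_id = rownames(table$intensities),
                    protein_group = table$peptides$protein_group,
                    icc_bio = icc_bio, icc_tech = icc_tech,
                    repeatability = icc_bio * icc_tech,
                    enrichment = e,
                    mean_A = mean_a, mean_B = mean_b,
                    degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("peptide_scores", "data.frame")
  out
}

#' Write peptide scores to TSV
#' @param scores a `peptide_scores` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peptide_scores <- function(scores, path) {
  utils::write.table(format(scores, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
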