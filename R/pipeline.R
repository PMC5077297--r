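#' Run the peptide-based core-glycoprotein pipeline end to end
#'
#' Normalize (optional) -> zero-impute -> score every peptide
#' (repeatability x enrichment) -> hierarchical clustering at `cut_height`
#' -> select the natural cluster -> call protein groups -> retrospective
#' Kolmogorov-Smirnov validation.
#'
#' @param table a `peptide_table`.
#' @param normalize apply [normalize_runs()] first.
#' @param cut_height dendrogram cut height for [cluster_peptides()].
#' @param linkage clustering linkage.
#' @param min_peptides selected peptides required per protein call.
#' @return a list of class `lfq_pipeline` with `scores`, `assignment`,
#'   `calls`, `core_proteins` (character vector) and `ks` (retrospective
#'   validation, `NULL` when one class is empty).
#' @export
run_peptide_pipeline <- function(table, normalize = TRUE, cut_height = 0.2,
                                 linkage = "single", min_peptides = 1) {
  stopifnot(inherits(table, "peptide_table"))
  if (normalize) table <- normalize_runs(table)
  table <- impute_missing_as_zero(table)
  scores <- score_all_peptides(table)
  assignment <- select_natural_cluster(
    cluster_peptides(scores, cut_height = cut_height, linkage = linkage))
  calls <- call_protein_groups(assignment, table,
                               min_peptides = min_peptides)
  core <- calls$protein_group[calls$call == "core_glycosylated"]
  ks <- tryCatch(retrospective_ks(scores, calls), error = function(e) NULL)
  structure(list(scores = scores, assignment = assignment, calls = calls,
                 core_proteins = core, ks = ks),
            class = "lfq_pipeline")
}

#' @export
print.lfq_pipeline <- function(x, ...) {
  cat(sprintf(
    "peptide-based LFQ pipeline: %d peptides, %d clusters, %d/%d protein groups called core-glycosylated\n",
    nrow(x$scores), nrow(x$assignment$clusters),
    length(x$core_proteins), nrow(x$calls)))
  if (!is.null(x$ks))
    cat(sprintf("  retrospective KS: D(e) = %.3f, D(r) = %.3f\n",
                x$ks$D_enrichment, x$ks$D_repeatability))
  invisible(x)
}

#' Confusion summary of protein calls against simulation ground truth
#'
#' @param calls a `protein_calls` data.frame.
#' @param truth the `truth` element returned by [simulate_peptide_table()].
#' @return a list with `tp`, `fp`, `fn`, `tn`, `sensitivity` and `fdp`
#'   (false-discovery proportion; 0 when nothing is called).
#' @export
evaluate_calls <- function(calls, truth) {
  tr <- truth$proteins
  called <- calls$protein_group[calls$call == "core_glycosylated"]
  targets <- tr$protein_group[tr$is_target]
  non_targets <- tr$protein_group[!tr$is_target]
  tp <- length(intersect(called, targets))
  fp <- length(intersect(called, non_targets))
  fn <- length(setdiff(targets, called))
  tn <- length(setdiff(non_targets, called))
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sensitivity = if (length(targets)) tp / length(targets) else NA_real_,
       fdp = if (tp + fp > 0) fp / (tp + fp) else 0)
}
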