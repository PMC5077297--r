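#' Hierarchical clustering of peptides in (repeatability, enrichment) space
#'
#' Agglomerative clustering of the 2-D peptide scores with Euclidean distance
#' and the given linkage; the dendrogram is cut at height `cut_height`
#' (default 0.2, in the raw units of the unit-bounded score plane). Cluster
#' labels are renumbered by decreasing centroid mean of (repeatability,
#' enrichment) so that labels are stable under permutations of the input.
#'
#' @param scores a `peptide_scores` data.frame from [score_all_peptides()].
#' @param cut_height dendrogram cut height.
#' @param linkage linkage method passed to [stats::hclust()]. The default,
#'   single linkage, makes the cut equivalent to thresholding the pairwise
#'   distance matrix at `cut_height` (clusters are the connected components
#'   of the "closer than 0.2" graph), which keeps the dense high-enrichment
#'   band intact even though per-peptide ICC estimates spread widely under
#'   few-biological-replicate designs; average/complete/ward.D2 remain
#'   available.
#' @return a list of class `cluster_assignment` with elements `peptides`
#'   (data.frame `peptide_id`, `cluster`, `selected`), `clusters` (data.frame
#'   `cluster`, `centroid_r`, `centroid_e`, `size`, `selected`) and the cut
#'   parameters. No cluster is selected yet; see [select_natural_cluster()].
#' @export
cluster_peptides <- function(scores, cut_height = 0.2, linkage = "single") {
  stopifnot(is.data.frame(scores),
            all(c("peptide_id", "repeatability", "enrichment") %in%
                  names(scores)))
  pts <- as.matrix(scores[, c("repeatability", "enrichment")])
  n <- nrow(pts)
  if (n == 0) stop("no scored peptides to cluster", call. = FALSE)
  if (n == 1) {
    warning("single peptide: one trivial cluster")
    labels <- 1L
  } else {
    # order-independent tie-breaking: cluster on sorted points, map back
    ord <- order(pts[, 1], pts[, 2], scores$peptide_id)
    hc <- stats::hclust(stats::dist(pts[ord, , drop = FALSE],
                                    method = "euclidean"),
                        method = linkage)
    labels_sorted <- if (is.finite(cut_height))
      stats::cutree(hc, h = cut_height)
    else rep(1L, n)
    labels <- integer(n)
    labels[ord] <- labels_sorted
  }
  cent_r <- tapply(pts[, 1], labels, mean)
  cent_e <- tapply(pts[, 2], labels, mean)
  size <- tabulate(labels)[as.integer(names(cent_r))]
  # relabel clusters by decreasing centroid quality for stable output
  quality <- (cent_r + cent_e) / 2
  new_order <- order(-quality, -cent_e, -size, as.integer(names(cent_r)))
  relabel <- stats::setNames(seq_along(new_order),
                             names(cent_r)[new_order])
  labels <- unname(relabel[as.character(labels)])
  clusters <- data.frame(cluster = seq_along(new_order),
                         centroid_r = unname(cent_r[new_order]),
                         centroid_e = unname(cent_e[new_order]),
                         size = unname(size[new_order]),
                         selected = FALSE)
  out <- list(peptides = data.frame(peptide_id = scores$peptide_id,
                                    cluster = labels, selected = FALSE,
                                    stringsAsFactors = FALSE),
              clusters = clusters,
              cut_height = cut_height, linkage = linkage)
  class(out) <- "cluster_assignment"
  out
}

#' Select the natural high-confidence cluster
#'
#' The natural cluster is the one jointly highest in repeatability and
#' enrichment: the cluster whose centroid maximizes
#' `(centroid_r + centroid_e) / 2`. Ties are broken by larger centroid
#' enrichment, then by larger cluster size. The selection is recorded in the
#' assignment.
#'
#' @param assignment a `cluster_assignment` from [cluster_peptides()].
#' @return the updated assignment, with attribute `selected_cluster` giving
#'   the chosen label.
#' @export
select_natural_cluster <- function(assignment) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  cl <- assignment$clusters
  quality <- (cl$centroid_r + cl$centroid_e) / 2
  best <- order(-quality, -cl$centroid_e, -cl$size)[1]
  label <- cl$cluster[best]
  assignment$clusters$selected <- cl$cluster == label
  assignment$peptides$selected <- assignment$peptides$cluster == label
  attr(assignment, "selected_cluster") <- label
  assignment
}

#' Call protein groups as core-glycosylated or background
#'
#' A protein group is called core-glycosylated when at least `min_peptides`
#' of its member peptides fall in the selected natural cluster; otherwise it
#' is background.
#'
#' @param assignment a selected `cluster_assignment`
#'   (after [select_natural_cluster()]).
#' @param table the `peptide_table` the scores came from (supplies the
#'   peptide to protein-group mapping).
#' @param min_peptides minimum selected peptides for a positive call.
#' @return a `protein_calls` data.frame with columns `protein_group`,
#'   `n_peptides`, `n_selected_peptides`, `call`.
#' @export
call_protein_groups <- function(assignment, table, min_peptides = 1) {
  stopifnot(inherits(assignment, "cluster_assignment"),
            inherits(table, "peptide_table"))
  if (!any(assignment$clusters$selected))
    stop("no cluster selected; run select_natural_cluster() first",
         call. = FALSE)
  idx <- match(assignment$peptides$peptide_id, table$peptides$peptide_id)
  if (anyNA(idx))
    stop("peptide(s) with no protein group in the table: ",
         paste(assignment$peptides$peptide_id[is.na(idx)][
           seq_len(min(5, sum(is.na(idx))))], collapse = ", "),
         call. = FALSE)
  group <- table$peptides$protein_group[idx]
  n_pep <- table(group)
  n_sel <- tapply(assignment$peptides$selected, group, sum)
  groups <- names(n_pep)
  out <- data.frame(
    protein_group = groups,
    n_peptides = as.integer(n_pep[groups]),
    n_selected_peptides = as.integer(n_sel[groups]),
    call = ifelse(n_sel[groups] >= min_peptides,
                  "core_glycosylated", "background"),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("protein_calls", "data.frame")
  out
}

#' Retrospective Kolmogorov-Smirnov validation of the protein calls
#'
#' Compares all peptides belonging to core-glycosylated-called proteins
#' against all remaining peptides, separately on the enrichment statistic
#' and on the repeatability index, with the two-sample Kolmogorov-Smirnov
#' test. On a successful selection the called proteins' peptides
#' stochastically dominate the background in both coordinates.
#'
#' @param scores a `peptide_scores` data.frame.
#' @param calls a `protein_calls` data.frame.
#' @return a list with `D_enrichment`, `p_enrichment`, `D_repeatability`,
#'   `p_repeatability`, and the two sample sizes. P-values are approximate in
#'   the presence of ties (zero-imputed intensities commonly tie scores).
#' @export
retrospective_ks <- function(scores, calls) {
  stopifnot(is.data.frame(scores), is.data.frame(calls))
  core <- calls$protein_group[calls$call == "core_glycosylated"]
  in_core <- scores$protein_group %in% core
  if (!any(in_core) || all(in_core))
    stop("retrospective test undefined: one of the classes is empty",
         call. = FALSE)
  ks <- function(x, y) {
    res <- suppressWarnings(stats::ks.test(x, y))
    list(D = unname(res$statistic), p = res$p.value)
  }
  e <- ks(scores$enrichment[in_core], scores$enrichment[!in_core])
  r <- ks(scores$repeatability[in_core], scores$repeatability[!in_core])
  list(D_enrichment = e$D, p_enrichment = e$p,
       D_repeatability = r$D, p_repeatability = r$p,
       n_core = sum(in_core), n_background = sum(!in_core))
}
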