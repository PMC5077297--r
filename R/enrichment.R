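#' Build an annotation universe
#'
#' @param universe character vector of protein ids constituting the reference
#'   proteome (the role played by the 19,690-protein hippocampal list in the
#'   assay this package models).
#' @param annotations data.frame with columns `protein_id`, `category`.
#'   Members absent from the universe are dropped with a warning.
#' @return a list of class `annotation_universe` with `universe` (character)
#'   and `categories` (named list of character vectors).
#' @export
annotation_universe <- function(universe, annotations) {
  universe <- unique(as.character(universe))
  stopifnot(is.data.frame(annotations),
            all(c("protein_id", "category") %in% names(annotations)))
  outside <- !annotations$protein_id %in% universe
  if (any(outside)) {
    warning(sum(outside),
            " annotation member(s) outside the universe dropped")
    annotations <- annotations[!outside, ]
  }
  categories <- split(as.character(annotations$protein_id),
                      as.character(annotations$category))
  categories <- lapply(categories, unique)
  structure(list(universe = universe, categories = categories),
            class = "annotation_universe")
}

#' Exact hypergeometric over-representation of one category
#'
#' Upper-tail hypergeometric test of the overlap between the selected
#' protein set and a category within a finite universe:
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` with `N` the universe
#' size, `K` the category size, `n` the selected-set size and `k` the
#' overlap. Fold enrichment is the observed relative frequency over the
#' expected one, `(k / n) / (K / N)`. Computation is exact
#' ([stats::phyper()]); no normal approximation is involved.
#'
#' Selected proteins absent from the universe are, by default, appended to
#' it (a double-purified set can contain proteins missed by the reference
#' list); set `extend_universe = FALSE` to drop them instead.
#'
#' @param selected character vector of selected protein ids.
#' @param universe an [annotation_universe()].
#' @param category name of the category to test.
#' @param extend_universe append out-of-universe selected proteins to the
#'   universe (default) rather than dropping them.
#' @return a one-row `enrichment_result` data.frame with columns `category`,
#'   `N`, `K`, `n`, `k`, `fold`, `p`.
#' @export
hypergeom_enrich <- function(selected, universe, category,
                             extend_universe = TRUE) {
  stopifnot(inherits(universe, "annotation_universe"))
  if (!category %in% names(universe$categories))
    stop("unknown category: ", category, call. = FALSE)
  selected <- unique(as.character(selected))
  uni <- universe$universe
  outsiders <- setdiff(selected, uni)
  if (length(outsiders)) {
    if (extend_universe) {
      message(length(outsiders),
              " selected protein(s) absent from the universe were added")
      uni <- c(uni, outsiders)
    } else {
      warning(length(outsiders),
              " selected protein(s) outside the universe dropped")
      selected <- intersect(selected, uni)
    }
  }
  members <- intersect(universe$categories[[category]], uni)
  N <- length(uni)
  K <- length(members)
  n <- length(selected)
  if (n == 0 || K == 0)
    stop("enrichment undefined: empty selected set or empty category",
         call. = FALSE)
  k <- length(intersect(selected, members))
  fold <- if (k > 0) (k / n) / (K / N) else 0
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(category = category, N = N, K = K, n = n, k = k,
                    fold = fold, p = p, stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` category members in `n` draws without replacement from a
#' universe of `N` containing `K` members. This is the exact tail used by
#' [hypergeom_enrich()]; exposed so the tail can be computed without
#' constructing protein sets. Vectorized over `k`.
#'
#' @param N,K,n universe size, category size, number of draws.
#' @param k observed overlap(s).
#' @return upper-tail probabilities.
#' @export
hypergeom_tail <- function(N, K, n, k) {
  stopifnot(K <= N, n <= N, K >= 0, n >= 0)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Test every category of a universe
#'
#' @inheritParams hypergeom_enrich
#' @param adjust apply Benjamini-Hochberg correction and add a `p_adj`
#'   column (raw p-values are always reported).
#' @return an `enrichment_result` data.frame, one row per category, sorted
#'   by p-value.
#' @export
enrich_all_categories <- function(selected, universe, extend_universe = TRUE,
                                  adjust = FALSE) {
  stopifnot(inherits(universe, "annotation_universe"))
  rows <- lapply(names(universe$categories), function(cat)
    hypergeom_enrich(selected, universe, cat,
                     extend_universe = extend_universe))
  out <- do.call(rbind, rows)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Class frequencies of a selected set versus a reference set
#'
#' Partitions both sets into the given classes (proteins covered by none go
#' to `"unclassified"`), reports the within-set relative frequency of each
#' class, and tests each class's representation in the selected set against
#' the reference with the exact hypergeometric test (reference set as
#' universe). Frequencies sum to 1 within each set. One-sided
#' (over-representation) by default; `two_sided = TRUE` doubles the smaller
#' tail (capped at 1).
#'
#' @param selected,reference character vectors of protein ids; `selected`
#'   should be contained in `reference` (outsiders are added to the
#'   reference with a message).
#' @param classes named list of character vectors partitioning the proteins
#'   (e.g. soluble / transmembrane / predicted N-glycoprotein). A protein in
#'   several classes is assigned to the first that contains it.
#' @param two_sided report two-sided p-values.
#' @return a data.frame with columns `class`, `freq_selected`,
#'   `freq_reference`, `k`, `K`, `p`, `minus_log10_p`.
#' @export
category_frequencies <- function(selected, reference, classes,
                                 two_sided = FALSE) {
  selected <- unique(as.character(selected))
  reference <- unique(as.character(reference))
  if (!length(selected) || !length(reference))
    stop("empty protein set", call. = FALSE)
  outsiders <- setdiff(selected, reference)
  if (length(outsiders)) {
    message(length(outsiders),
            " selected protein(s) absent from the reference were added")
    reference <- c(reference, outsiders)
  }
  assign_class <- function(ids) {
    lab <- rep("unclassified", length(ids))
    for (cl in rev(names(classes)))
      lab[ids %in% classes[[cl]]] <- cl
    lab
  }
  class_names <- c(names(classes), "unclassified")
  sel_lab <- factor(assign_class(selected), levels = class_names)
  ref_lab <- factor(assign_class(reference), levels = class_names)
  k <- as.integer(table(sel_lab))
  K <- as.integer(table(ref_lab))
  N <- length(reference)
  n <- length(selected)
  p_upper <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p <- if (two_sided) {
    p_lower <- stats::phyper(k, K, N - K, n, lower.tail = TRUE)
    pmin(1, 2 * pmin(p_upper, p_lower))
  } else p_upper
  keep <- K > 0 | k > 0
  data.frame(class = class_names,
             freq_selected = k / n,
             freq_reference = K / N,
             k = k, K = K, p = p,
             minus_log10_p = -log10(p),
             stringsAsFactors = FALSE)[keep, , drop = FALSE]
}
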