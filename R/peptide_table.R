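#' Assemble a peptide intensity table
#'
#' The central container of the package: a peptides x runs intensity matrix
#' together with peptide-to-protein-group membership and the replicate design
#' of the runs. Missing intensities are encoded as `NA` and kept distinct from
#' zero until [impute_missing_as_zero()] collapses them by policy.
#'
#' @param intensities numeric matrix, peptides in rows (rownames are peptide
#'   ids), runs in columns (colnames are run ids). Values are non-negative
#'   arbitrary intensity units; `NA` means not detected in that run.
#' @param peptides data.frame with columns `peptide_id` and `protein_group`
#'   (optionally `sequence`), one row per row of `intensities`.
#' @param design data.frame describing the runs; see [replicate_design()].
#'
#' @return an object of class `peptide_table` with elements `intensities`,
#'   `peptides`, `design` and the logical attribute `imputed` (`FALSE` until
#'   missing values are collapsed to zero).
#' @seealso [read_peptide_table()], [normalize_runs()], [score_all_peptides()]
#' @export
peptide_table <- function(intensities, peptides, design) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  storage.mode(intensities) <- "double"
  design <- replicate_design(design)
  if (is.null(rownames(intensities)))
    rownames(intensities) <- peptides$peptide_id
  if (anyDuplicated(peptides$peptide_id))
    stop("duplicate peptide_id: ",
         paste(unique(peptides$peptide_id[duplicated(peptides$peptide_id)]),
               collapse = ", "), call. = FALSE)
  if (nrow(intensities) != nrow(peptides))
    stop("`intensities` and `peptides` disagree on the number of peptides",
         call. = FALSE)
  if (!identical(rownames(intensities), as.character(peptides$peptide_id)))
    stop("rownames of `intensities` must match `peptides$peptide_id` in order",
         call. = FALSE)
  unknown <- setdiff(colnames(intensities), design$run_id)
  if (length(unknown))
    stop("runs absent from the design: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing_runs <- setdiff(design$run_id, colnames(intensities))
  if (length(missing_runs))
    stop("design runs absent from the table: ",
         paste(missing_runs, collapse = ", "), call. = FALSE)
  if (any(intensities < 0, na.rm = TRUE))
    stop("negative intensities are not allowed", call. = FALSE)
  # order columns as in the design so run-wise operations line up
  intensities <- intensities[, design$run_id, drop = FALSE]
  structure(
    list(intensities = intensities,
         peptides = as.data.frame(peptides, stringsAsFactors = FALSE),
         design = design),
    imputed = FALSE,
    class = "peptide_table"
  )
}

#' Validate a replicate design table
#'
#' The design maps every LC-MS run to its condition (`A`, lectin-bound target
#' without EndoH; `B`, EndoH-treated background), biological replicate
#' (independent neuronal preparation), experimental replicate (independent
#' affinity purification/digestion) and technical replicate (repeated LC-MS
#' injection).
#'
#' @param design data.frame with columns `run_id`, `condition`, `bio_rep`,
#'   `exp_rep`, `tech_rep`.
#' @return the validated design with character columns and a `prep` column
#'   identifying each biological x experimental preparation.
#' @export
replicate_design <- function(design) {
  required <- c("run_id", "condition", "bio_rep", "exp_rep", "tech_rep")
  absent <- setdiff(required, names(design))
  if (length(absent))
    stop("design is missing column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  for (col in required) design[[col]] <- as.character(design[[col]])
  bad <- setdiff(unique(design$condition), c("A", "B"))
  if (length(bad))
    stop("condition labels must be 'A' or 'B'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(design$run_id))
    stop("duplicate run_id in design: ",
         paste(unique(design$run_id[duplicated(design$run_id)]),
               collapse = ", "), call. = FALSE)
  design$prep <- paste(design$bio_rep, design$exp_rep, sep = ":")
  design
}

#' @export
print.peptide_table <- function(x, ...) {
  n_a <- sum(x$design$condition == "A")
  n_b <- sum(x$design$condition == "B")
  cat(sprintf(
    "peptide_table: %d peptides, %d protein groups, %d runs (%d A, %d B)\n",
    nrow(x$intensities), length(unique(x$peptides$protein_group)),
    ncol(x$intensities), n_a, n_b))
  cat(sprintf("  missing cells: %d (%.1f%%)%s\n",
              sum(is.na(x$intensities)),
              100 * mean(is.na(x$intensities)),
              if (isTRUE(attr(x, "imputed"))) " [imputed to zero]" else ""))
  invisible(x)
}

#' Read a peptide table and its replicate design from TSV files
#'
#' Expects a MaxQuant-peptides-style tab-delimited table: one row per peptide
#' with columns `peptide_id`, `protein_group`, optional `sequence`, and one
#' intensity column per run id, plus a design TSV (`run_id`, `condition`,
#' `bio_rep`, `exp_rep`, `tech_rep`). Empty cells and `NA` in intensity
#' columns are read as missing.
#'
#' @param table_path path to the peptide intensity TSV.
#' @param design_path path to the replicate design TSV.
#' @return a [peptide_table()].
#' @export
read_peptide_table <- function(table_path, design_path) {
  for (p in c(table_path, design_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  tab <- utils::read.delim(table_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  design <- utils::read.delim(design_path, check.names = FALSE,
                              stringsAsFactors = FALSE)
  meta_cols <- intersect(c("peptide_id", "protein_group", "sequence"),
                         names(tab))
  if (!all(c("peptide_id", "protein_group") %in% meta_cols))
    stop("peptide table must have columns peptide_id and protein_group",
         call. = FALSE)
  run_cols <- setdiff(names(tab), meta_cols)
  if (!length(run_cols))
    stop("peptide table has no intensity columns", call. = FALSE)
  intensities <- as.matrix(tab[, run_cols, drop = FALSE])
  storage.mode(intensities) <- "double"
  rownames(intensities) <- as.character(tab$peptide_id)
  peptides <- tab[, meta_cols, drop = FALSE]
  peptides$peptide_id <- as.character(peptides$peptide_id)
  peptides$protein_group <- as.character(peptides$protein_group)
  peptide_table(intensities, peptides, design)
}

#' Write a peptide table (and its design) to TSV files
#'
#' Inverse of [read_peptide_table()]: missing intensities are written as
#' empty cells. Numbers are written with full precision (15 significant
#' digits) so that a write/read round trip reproduces the table.
#'
#' @param table a `peptide_table`.
#' @param table_path,design_path output TSV paths; the design is only written
#'   when `design_path` is non-`NULL`.
#' @return `table_path`, invisibly.
#' @export
write_peptide_table <- function(table, table_path, design_path = NULL) {
  stopifnot(inherits(table, "peptide_table"))
  out <- data.frame(table$peptides,
                    signif(table$intensities, 15),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  if (!is.null(design_path)) {
    design <- table$design[, c("run_id", "condition", "bio_rep",
                               "exp_rep", "tech_rep")]
    utils::write.table(design, design_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(table_path)
}

#' Rescale runs to a common total intensity
#'
#' Total-sum normalization: each run is rescaled so that its summed observed
#' intensity equals the across-run median of summed observed intensities.
#' Missing entries are untouched. A run with no observed intensity keeps
#' scale 1, with a warning.
#'
#' @param table a `peptide_table`.
#' @return the normalized `peptide_table`; per-run scale factors are stored in
#'   the attribute `run_scales`.
#' @export
normalize_runs <- function(table) {
  stopifnot(inherits(table, "peptide_table"))
  sums <- colSums(table$intensities, na.rm = TRUE)
  observed <- colSums(!is.na(table$intensities)) > 0
  if (any(!observed))
    warning("run(s) with no observed intensity left unscaled: ",
            paste(colnames(table$intensities)[!observed], collapse = ", "))
  target <- stats::median(sums[observed])
  scales <- rep(1, length(sums))
  scales[observed] <- target / sums[observed]
  table$intensities <- sweep(table$intensities, 2, scales, `*`)
  attr(table, "run_scales") <- stats::setNames(scales,
                                               colnames(table$intensities))
  table
}

#' Collapse missing intensities to zero
#'
#' Absence of a peptide in a background (B) run is informative in this assay,
#' so downstream scoring treats missing as zero intensity. The policy is
#' recorded in the table's `imputed` attribute.
#'
#' @param table a `peptide_table`.
#' @return the table with every `NA` intensity replaced by 0 and
#'   `attr(, "imputed")` set to `TRUE`. The pre-imputation detection mask is
#'   kept in element `detected` so detection-based filters (see
#'   [standard_lfq_select()]) still see which cells were observed.
#' @export
impute_missing_as_zero <- function(table) {
  stopifnot(inherits(table, "peptide_table"))
  if (is.null(table$detected)) table$detected <- !is.na(table$intensities)
  table$intensities[is.na(table$intensities)] <- 0
  attr(table, "imputed") <- TRUE
  table
}

#' Detection mask of a peptide table
#'
#' `TRUE` where a peptide was observed (pre-imputation) in a run.
#' @param table a `peptide_table`.
#' @return logical matrix of the same shape as the intensities.
#' @export
detection_mask <- function(table) {
  if (!is.null(table$detected)) table$detected else !is.na(table$intensities)
}
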