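# Construct small peptide tables with an explicit 2-biological x
# 2-experimental replicate design for unit tests. `A` and `B` are
# peptides x runs matrices (NA = missing); run columns are assigned to
# biological and experimental replicates in blocks.
make_toy_table <- function(A, B, protein_group = NULL) {
  A <- rbind(A); B <- rbind(B)
  stopifnot(nrow(A) == nrow(B))
  n_pep <- nrow(A)
  block_design <- function(cond, n_runs) {
    bio <- rep(c("bio1", "bio2"), each = ceiling(n_runs / 2))[1:n_runs]
    exp <- unlist(lapply(split(seq_len(n_runs), bio), function(idx)
      rep(c("exp1", "exp2"), each = ceiling(length(idx) / 2))[
        seq_along(idx)]), use.names = FALSE)
    data.frame(run_id = sprintf("%s%02d", cond, seq_len(n_runs)),
               condition = cond, bio_rep = bio, exp_rep = exp,
               tech_rep = sprintf("tech%d", seq_len(n_runs)),
               stringsAsFactors = FALSE)
  }
  design <- rbind(block_design("A", ncol(A)), block_design("B", ncol(B)))
  m <- cbind(A, B)
  colnames(m) <- design$run_id
  if (is.null(protein_group)) protein_group <- sprintf("P%d", seq_len(n_pep))
  peptides <- data.frame(peptide_id = sprintf("pep%d", seq_len(n_pep)),
                         protein_group = protein_group,
                         stringsAsFactors = FALSE)
  rownames(m) <- peptides$peptide_id
  peptide_table(m, peptides, design)
}

# peptide_scores data.frame from bare (r, e) coordinates
make_scores <- function(r, e, protein_group = NULL) {
  n <- length(r)
  if (is.null(protein_group)) protein_group <- sprintf("P%d", seq_len(n))
  out <- data.frame(peptide_id = sprintf("pep%d", seq_len(n)),
                    protein_group = protein_group,
                    icc_bio = r, icc_tech = 1, repeatability = r,
                    enrichment = e, mean_A = 1, mean_B = 0,
                    degenerate = FALSE, stringsAsFactors = FALSE)
  class(out) <- c("peptide_scores", "data.frame")
  out
}
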