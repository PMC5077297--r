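#' Configuration for the peptide-level LFQ simulator
#'
#' Defines the study conditions emulated by [simulate_peptide_table()]: a
#' two-condition (A = lectin-bound target, B = EndoH-treated background)
#' label-free experiment with nested biological / experimental / technical
#' replication and log-normal peptide intensities.
#'
#' The default replicate design mirrors the assay this scoring was developed
#' for: 2 biological preparations x 2 affinity purifications each, injected
#' 3 or 4 times (`n_tech = c(3, 4, 3, 4)`), i.e. 14 LC-MS runs per condition.
#' Variance components are standard deviations of natural-log intensity:
#' `sigma_bio` acts per biological replicate, `sigma_exp` per preparation
#' (biological x experimental), `sigma_tech` per run. Target-protein peptides
#' are attenuated `target_B_attenuation`-fold in condition B and additionally
#' dropped (missing) with probability `dropout_B`, reproducing the
#' missing-value-rich, low-intensity background condition. `dropout_floor`
#' optionally censors any cell whose intensity falls below the given raw
#' threshold (0 disables it).
#'
#' @param n_proteins number of simulated protein groups.
#' @param frac_target fraction in \[0,1\] of proteins planted as
#'   core-glycosylated targets.
#' @param peptides_per_protein mean of the (zero-truncated Poisson) number of
#'   peptides per protein.
#' @param n_bio,n_exp biological replicates and experimental replicates per
#'   biological replicate.
#' @param n_tech integer vector of technical replicates per preparation
#'   (recycled over the `n_bio * n_exp` preparations), or a single count.
#' @param sigma_bio,sigma_exp,sigma_tech log-scale standard deviations of the
#'   nested variance components.
#' @param sigma_peptide log-scale standard deviation of per-peptide baseline
#'   abundance around `base_log_intensity`.
#' @param base_log_intensity mean natural-log intensity of a peptide.
#' @param target_B_attenuation multiplicative intensity reduction (> 1 means
#'   reduced) of target peptides in condition B.
#' @param dropout_B probability that a target-peptide cell in a B run is
#'   missing.
#' @param dropout_floor raw-intensity censoring threshold applied to all
#'   cells (0 = off).
#' @param background_noise_inflation factor multiplying the run-level
#'   `sigma_tech` for non-target peptides. Background binding is
#'   non-specific carry-over, which repeats less faithfully from injection
#'   to injection than genuine lectin-bound material; the default 2
#'   reproduces the characteristic low-repeatability background spread of
#'   the score plane while leaving condition means (and hence the
#'   enrichment statistic) nearly untouched, since run-level noise averages
#'   out across the 13-14 runs of a condition. Set to 1 for homogeneous
#'   noise.
#' @param shared_peptides if `TRUE`, a small fraction of peptides is assigned
#'   to two protein groups; off by default so peptide-to-protein rollup is
#'   unambiguous.
#' @param seed integer RNG seed; a fixed seed makes the output bit-identical.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 300,
                       frac_target = 0.1,
                       peptides_per_protein = 4,
                       n_bio = 2,
                       n_exp = 2,
                       n_tech = c(3, 4, 3, 4),
                       sigma_bio = 0.5,
                       sigma_exp = 0.3,
                       sigma_tech = 0.2,
                       sigma_peptide = 1.5,
                       base_log_intensity = 14,
                       target_B_attenuation = 10,
                       dropout_B = 0.5,
                       dropout_floor = 0,
                       background_noise_inflation = 2,
                       shared_peptides = FALSE,
                       seed = 1L) {
  cfg <- list(n_proteins = n_proteins, frac_target = frac_target,
              peptides_per_protein = peptides_per_protein,
              n_bio = n_bio, n_exp = n_exp, n_tech = n_tech,
              sigma_bio = sigma_bio, sigma_exp = sigma_exp,
              sigma_tech = sigma_tech, sigma_peptide = sigma_peptide,
              base_log_intensity = base_log_intensity,
              target_B_attenuation = target_B_attenuation,
              dropout_B = dropout_B, dropout_floor = dropout_floor,
              background_noise_inflation = background_noise_inflation,
              shared_peptides = isTRUE(shared_peptides),
              seed = as.integer(seed))
  .check_count <- function(x, name) {
    if (length(x) < 1 || any(!is.finite(x)) || any(x < 1) || any(x != round(x)))
      stop("invalid configuration: `", name, "` must be a count >= 1",
           call. = FALSE)
  }
  .check_count(cfg$n_proteins, "n_proteins")
  .check_count(cfg$n_bio, "n_bio")
  .check_count(cfg$n_exp, "n_exp")
  .check_count(cfg$n_tech, "n_tech")
  if (cfg$peptides_per_protein < 1)
    stop("invalid configuration: `peptides_per_protein` must be >= 1",
         call. = FALSE)
  for (f in c("frac_target", "dropout_B")) {
    v <- cfg[[f]]
    if (!is.finite(v) || v < 0 || v > 1)
      stop("invalid configuration: `", f, "` must be a fraction in [0,1]",
           call. = FALSE)
  }
  for (s in c("sigma_bio", "sigma_exp", "sigma_tech", "sigma_peptide")) {
    if (!is.finite(cfg[[s]]) || cfg[[s]] < 0)
      stop("invalid configuration: `", s, "` must be >= 0", call. = FALSE)
  }
  if (!is.finite(cfg$target_B_attenuation) || cfg$target_B_attenuation <= 0)
    stop("invalid configuration: `target_B_attenuation` must be > 0",
         call. = FALSE)
  if (!is.finite(cfg$background_noise_inflation) ||
      cfg$background_noise_inflation <= 0)
    stop("invalid configuration: `background_noise_inflation` must be > 0",
         call. = FALSE)
  if (cfg$dropout_floor < 0)
    stop("invalid configuration: `dropout_floor` must be >= 0", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# Replicate design for one condition: runs labelled by bio/exp/tech indices.
.condition_design <- function(condition, n_bio, n_exp, n_tech) {
  n_prep <- n_bio * n_exp
  tech_counts <- rep_len(n_tech, n_prep)
  rows <- list()
  p <- 0L
  for (b in seq_len(n_bio)) {
    for (e in seq_len(n_exp)) {
      p <- p + 1L
      for (t in seq_len(tech_counts[p])) {
        rows[[length(rows) + 1L]] <- data.frame(
          run_id = sprintf("%s_b%d_e%d_t%d", condition, b, e, t),
          condition = condition,
          bio_rep = sprintf("bio%d", b),
          exp_rep = sprintf("exp%d", e),
          tech_rep = sprintf("tech%d", t),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Simulate a peptide intensity table with planted core-glycosylated targets
#'
#' Draws log-normal peptide intensities with additive nested variance
#' components on the log scale (biological, experimental/preparation,
#' technical), attenuates and drops target-protein peptides in the background
#' condition B, and returns the table together with the ground truth of which
#' proteins were planted as targets.
#'
#' The biological effect of a peptide is shared between the A and B runs of
#' the same biological preparation (both conditions start from the same
#' surface proteome); experimental and technical effects are drawn per
#' condition, since A and B are purified and injected separately.
#'
#' @param config a [sim_config()].
#' @return a list with elements `table` (a [peptide_table()], missing cells
#'   `NA`) and `truth` (a list with `proteins`: data.frame `protein_group`,
#'   `is_target`; and `peptides`: data.frame `peptide_id`, `protein_group`,
#'   `is_target`).
#' @export
simulate_peptide_table <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)

  n_targets <- round(config$n_proteins * config$frac_target)
  protein_ids <- sprintf("P%04d", seq_len(config$n_proteins))
  is_target <- c(rep(TRUE, n_targets),
                 rep(FALSE, config$n_proteins - n_targets))

  # zero-truncated Poisson peptide counts
  n_pep <- stats::rpois(config$n_proteins,
                        lambda = config$peptides_per_protein - 1) + 1L
  pep_protein <- rep(protein_ids, n_pep)
  pep_target <- rep(is_target, n_pep)
  n_peptides <- length(pep_protein)
  peptide_ids <- sprintf("pep%05d", seq_len(n_peptides))

  protein_group <- pep_protein
  if (config$shared_peptides && config$n_proteins > 1) {
    shared <- stats::runif(n_peptides) < 0.05
    if (any(shared)) {
      partner <- protein_ids[
        1 + (match(pep_protein[shared], protein_ids)) %% config$n_proteins]
      protein_group[shared] <- paste(pep_protein[shared], partner, sep = ";")
    }
  }

  design <- rbind(
    .condition_design("A", config$n_bio, config$n_exp, config$n_tech),
    .condition_design("B", config$n_bio, config$n_exp, config$n_tech))
  design$prep <- paste(design$bio_rep, design$exp_rep, sep = ":")
  n_runs <- nrow(design)

  mu <- stats::rnorm(n_peptides, config$base_log_intensity,
                     config$sigma_peptide)

  # nested random effects on the log scale
  bio_levels <- sort(unique(design$bio_rep))
  bio_eff <- matrix(stats::rnorm(n_peptides * length(bio_levels),
                                 0, config$sigma_bio),
                    n_peptides, length(bio_levels),
                    dimnames = list(NULL, bio_levels))
  # non-specific background binding repeats less faithfully across
  # purifications and injections: inflate its prep/run components
  infl <- ifelse(pep_target, 1, config$background_noise_inflation)
  prep_levels <- unique(design[, c("condition", "prep")])
  prep_key <- paste(prep_levels$condition, prep_levels$prep)
  prep_eff <- matrix(stats::rnorm(n_peptides * length(prep_key),
                                  0, config$sigma_exp),
                     n_peptides, length(prep_key),
                     dimnames = list(NULL, prep_key))

  log_int <- matrix(0, n_peptides, n_runs,
                    dimnames = list(peptide_ids, design$run_id))
  for (j in seq_len(n_runs)) {
    log_int[, j] <- mu +
      bio_eff[, design$bio_rep[j]] +
      prep_eff[, paste(design$condition[j], design$prep[j])] +
      stats::rnorm(n_peptides, 0, config$sigma_tech * infl)
  }

  b_runs <- design$condition == "B"
  if (any(pep_target) && any(b_runs)) {
    log_int[pep_target, b_runs] <-
      log_int[pep_target, b_runs] - log(config$target_B_attenuation)
  }
  intensities <- exp(log_int)

  # informative missingness: Bernoulli dropout of target peptides in B
  if (config$dropout_B > 0 && any(pep_target) && any(b_runs)) {
    n_cells <- sum(pep_target) * sum(b_runs)
    drop <- matrix(stats::runif(n_cells) < config$dropout_B,
                   sum(pep_target), sum(b_runs))
    intensities[pep_target, b_runs][drop] <- NA_real_
  }
  if (config$dropout_floor > 0)
    intensities[!is.na(intensities) &
                  intensities < config$dropout_floor] <- NA_real_

  peptides <- data.frame(peptide_id = peptide_ids,
                         protein_group = protein_group,
                         stringsAsFactors = FALSE)
  truth <- list(
    proteins = data.frame(protein_group = protein_ids, is_target = is_target,
                          stringsAsFactors = FALSE),
    peptides = data.frame(peptide_id = peptide_ids,
                          protein_group = protein_group,
                          is_target = pep_target, stringsAsFactors = FALSE))
  list(table = peptide_table(intensities, peptides, design), truth = truth)
}

#' Simulate a pulse-chase decay series per glycoform
#'
#' Expected intensity of each form follows first-order decay,
#' `I0 * 2^(-t / t_half)`, with multiplicative log-normal noise of the given
#' coefficient of variation. Optionally includes a `total` series equal to
#' the sum of the form intensities, as measured when glycoforms are not
#' resolved on the blot.
#'
#' @param half_lives named numeric vector of half-lives in hours, one per
#'   glycoform (e.g. `c(core = 3.4, mature = 21.1)`).
#' @param times chase times in hours, non-negative and sorted.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (0 = noise-free).
#' @param n_rep number of replicate series.
#' @param I0 intensity at time 0 (same for every form).
#' @param include_total add a `total` form summing the others.
#' @param seed integer RNG seed.
#' @return a `decay_series` data.frame with columns `replicate`, `time_h`,
#'   `form`, `intensity`.
#' @export
simulate_decay_series <- function(half_lives, times, noise_cv = 0,
                                  n_rep = 1, I0 = 100,
                                  include_total = FALSE, seed = 1L) {
  if (any(!is.finite(half_lives)) || any(half_lives <= 0))
    stop("half-lives must be positive and finite", call. = FALSE)
  if (any(times < 0) || is.unsorted(times))
    stop("times must be non-negative and sorted", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (is.null(names(half_lives)))
    names(half_lives) <- sprintf("form%d", seq_along(half_lives))
  set.seed(as.integer(seed))
  sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
  rows <- list()
  for (r in seq_len(n_rep)) {
    clean <- sapply(half_lives, function(th) I0 * 2^(-times / th))
    clean <- matrix(clean, nrow = length(times),
                    dimnames = list(NULL, names(half_lives)))
    noisy <- clean
    if (sdlog > 0)
      noisy <- clean * exp(matrix(stats::rnorm(length(clean), 0, sdlog),
                                  nrow = nrow(clean)))
    for (f in names(half_lives)) {
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, time_h = times, form = f, intensity = noisy[, f],
        stringsAsFactors = FALSE)
    }
    if (include_total) {
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, time_h = times, form = "total",
        intensity = rowSums(noisy), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("decay_series", "data.frame")
  out
}

#' Simulate a surface / intracellular fractionation measurement
#'
#' Generates band intensities `S` (surface fraction, loaded at dilution
#' `1/a`) and `I` (intracellular fraction, dilution `1/b`) whose noise-free
#' relative surface expression `S / (S + b * I / a)` equals `true_rse`.
#'
#' @param true_rse true relative surface expression in \[0,1\].
#' @param a,b positive reciprocals of the dilution factors `1/a` (surface)
#'   and `1/b` (intracellular).
#' @param noise_cv coefficient of variation of multiplicative log-normal
#'   measurement noise on each band.
#' @param total total protein amount in arbitrary units.
#' @param seed integer RNG seed.
#' @return a list of class `surface_fractions` with fields `S`, `I`, `a`, `b`.
#' @export
simulate_surface_fractions <- function(true_rse, a = 1, b = 1,
                                       noise_cv = 0, total = 1000,
                                       seed = 1L) {
  if (!is.finite(true_rse) || true_rse < 0 || true_rse > 1)
    stop("true_rse must be in [0,1]", call. = FALSE)
  if (a <= 0 || b <= 0) stop("dilution parameters a, b must be > 0",
                             call. = FALSE)
  set.seed(as.integer(seed))
  surface_amount <- true_rse * total
  internal_amount <- (1 - true_rse) * total
  noise <- function() {
    if (noise_cv > 0) exp(stats::rnorm(1, 0, sqrt(log(1 + noise_cv^2))))
    else 1
  }
  m <- list(S = surface_amount / a * noise(),
            I = internal_amount / b * noise(),
            a = a, b = b)
  class(m) <- "surface_fractions"
  m
}
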