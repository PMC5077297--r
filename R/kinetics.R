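#' Half-life of one glycoform from a pulse-chase decay series
#'
#' First-order decay is fit on the log scale: ordinary least squares of
#' `ln(intensity)` on chase time, per replicate. The decay rate is
#' `lambda = -slope` (1/h) and the half-life `t_half = ln(2) / lambda`
#' (hours). Per-replicate estimates are aggregated as mean +/- SEM of the
#' half-life. Zero or negative intensities carry no log information and are
#' excluded from the fit, with their count reported. A non-decaying series
#' (`lambda <= 0`) is reported with an infinite half-life and flagged, not
#' raised as an error.
#'
#' @param series a `decay_series` data.frame (columns `replicate`, `time_h`,
#'   `form`, `intensity`), e.g. from [simulate_decay_series()].
#' @param form which glycoform to fit (`"core"`, `"mature"`, `"total"`, ...).
#' @param method `"loglinear"` (default, matches log-scale decay plots) or
#'   `"nls"`, nonlinear least squares of
#'   `I0 * exp(-lambda * t) + offset` with a floor offset for blot
#'   background.
#' @return a list of class `half_life_fit` with `half_life`, `lambda`
#'   (means over replicates), `sem` (SEM of the half-life across replicates,
#'   `NA` for a single replicate), `per_replicate` (data.frame), `n_dropped`
#'   (non-positive intensities excluded) and `non_decaying` (flag).
#' @export
fit_half_life <- function(series, form = NULL,
                          method = c("loglinear", "nls")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(series),
            all(c("replicate", "time_h", "intensity") %in% names(series)))
  if (!is.null(form)) {
    if (!"form" %in% names(series))
      stop("series has no `form` column", call. = FALSE)
    series <- series[series$form == form, , drop = FALSE]
    if (!nrow(series)) stop("form not present in series: ", form,
                            call. = FALSE)
  }
  n_dropped <- sum(series$intensity <= 0)
  series <- series[series$intensity > 0, , drop = FALSE]
  fits <- lapply(split(series, series$replicate), function(d) {
    if (nrow(d) < 3 || length(unique(d$time_h)) < 2)
      stop("need >= 3 positive points spanning > 0 time per replicate",
           call. = FALSE)
    if (method == "loglinear") {
      lambda <- -unname(stats::coef(stats::lm(log(intensity) ~ time_h,
                                              data = d))[2])
    } else {
      start <- list(I0 = max(d$intensity),
                    lambda = log(2) / max(diff(range(d$time_h)), 1),
                    offset = 0)
      fit <- minpack.lm::nlsLM(
        intensity ~ I0 * exp(-lambda * time_h) + offset,
        data = d, start = start,
        lower = c(I0 = 0, lambda = -Inf, offset = 0))
      lambda <- unname(stats::coef(fit)[["lambda"]])
    }
    data.frame(replicate = d$replicate[1], lambda = lambda,
               half_life = if (lambda > 0) log(2) / lambda else Inf)
  })
  per_rep <- do.call(rbind, fits)
  rownames(per_rep) <- NULL
  hl <- per_rep$half_life
  lambda_mean <- mean(per_rep$lambda)
  out <- list(
    half_life = if (all(is.finite(hl))) mean(hl) else Inf,
    lambda = lambda_mean,
    sem = if (nrow(per_rep) > 1 && all(is.finite(hl)))
      stats::sd(hl) / sqrt(length(hl)) else NA_real_,
    per_replicate = per_rep,
    n_dropped = n_dropped,
    non_decaying = lambda_mean <= 0,
    method = method)
  class(out) <- "half_life_fit"
  out
}

#' @export
print.half_life_fit <- function(x, ...) {
  cat(sprintf("half-life: %.3g h (lambda = %.4g /h, %d replicate%s%s)\n",
              x$half_life, x$lambda, nrow(x$per_replicate),
              if (nrow(x$per_replicate) > 1) "s" else "",
              if (is.na(x$sem)) "" else sprintf(", SEM %.3g h", x$sem)))
  if (x$non_decaying) cat("  flag: series does not decay (lambda <= 0)\n")
  invisible(x)
}

#' Compare the turnover of core, mature and total glycoform pools
#'
#' Fits [fit_half_life()] to each glycoform present among `core`, `mature`
#' and `total` and reports the half-lives, their ordering and the
#' core:mature decay-rate ratio. Missing forms give a partial result with a
#' flag rather than an error.
#'
#' @param series a `decay_series` data.frame with a `form` column.
#' @param method fit method passed to [fit_half_life()].
#' @return a list with `fits` (named list of `half_life_fit`), `half_lives`
#'   (named numeric), `lambda_ratio_core_mature`, `core_faster` (logical)
#'   and `missing_forms`.
#' @export
compare_glycoform_turnover <- function(series, method = "loglinear") {
  stopifnot(is.data.frame(series), "form" %in% names(series))
  wanted <- c("core", "mature", "total")
  present <- intersect(wanted, unique(series$form))
  missing_forms <- setdiff(wanted, present)
  if (!length(present)) stop("no known glycoform in series", call. = FALSE)
  # an absent total pool is ordinary (glycoforms resolved on the blot);
  # a missing resolved form makes the comparison partial
  if (length(setdiff(missing_forms, "total")))
    warning("form(s) absent, partial result: ",
            paste(setdiff(missing_forms, "total"), collapse = ", "))
  fits <- lapply(present, function(f) fit_half_life(series, form = f,
                                                    method = method))
  names(fits) <- present
  hl <- vapply(fits, function(f) f$half_life, 1)
  ratio <- if (all(c("core", "mature") %in% present))
    fits$core$lambda / fits$mature$lambda else NA_real_
  list(fits = fits, half_lives = hl,
       lambda_ratio_core_mature = ratio,
       core_faster = if (is.na(ratio)) NA else unname(ratio > 1),
       missing_forms = missing_forms)
}

#' Peak and decay kinetics of a stimulus-response fluorescence trace
#'
#' For a baseline-normalized trace with a known stimulus onset: the peak is
#' the global post-onset maximum and time-to-peak is measured from onset.
#' The post-peak segment is normalized to the peak and fit with the
#' mono-exponential plateau model
#' `f(t) = plateau + (1 - plateau) * exp(-t / tau)` (t measured from the
#' peak), so `plateau` is the fraction of the peak the response relaxes to
#' and `tau` the decay time constant. Internally the decay amplitude is a
#' free parameter (`p0 + amp * exp(-t / tau)`) and the plateau fraction is
#' taken relative to the fitted peak `p0 + amp`, so measurement noise on
#' the single maximum sample does not bias the estimates. A response that
#' does not decay (plateau indistinguishable from 1) leaves `tau`
#' unidentifiable; it is returned as `NA` with `flat = TRUE`.
#'
#' @param time,fluorescence numeric vectors of the trace (seconds,
#'   baseline-normalized arbitrary units).
#' @param onset stimulus-onset time in seconds (an explicit input, never
#'   inferred from the trace).
#' @param flat_tol the fit is declared flat when the post-peak decay
#'   amplitude `1 - plateau` is below this fraction.
#' @return a list of class `response_fit` with `time_to_peak`, `peak`,
#'   `plateau`, `tau`, `flat`.
#' @export
response_kinetics <- function(time, fluorescence, onset = 0,
                              flat_tol = 1e-3) {
  stopifnot(length(time) == length(fluorescence), !is.unsorted(time))
  post <- time >= onset
  if (sum(post) < 4) stop("too few post-onset samples", call. = FALSE)
  t_post <- time[post]
  f_post <- fluorescence[post]
  ipk <- which.max(f_post)
  if (ipk == length(f_post))
    stop("no peak: trace is still rising at the last sample", call. = FALSE)
  peak <- f_post[ipk]
  if (peak <= 0) stop("non-positive peak fluorescence", call. = FALSE)
  time_to_peak <- t_post[ipk] - onset
  td <- t_post[ipk:length(t_post)] - t_post[ipk]
  fd <- f_post[ipk:length(f_post)] / peak
  if (length(td) < 3) stop("too few post-peak samples to fit the decay",
                           call. = FALSE)
  span <- max(td)
  # the decay amplitude is fit rather than pinned to the observed maximum,
  # so a noisy peak sample does not bias tau; the plateau fraction is then
  # taken relative to the fitted peak value (p0 + amp)
  amp0 <- max(1 - min(fd), 0)
  if (amp0 < flat_tol) {
    plateau <- mean(fd); tau <- NA_real_; flat <- TRUE
  } else {
    fit <- minpack.lm::nlsLM(
      fd ~ p0 + amp * exp(-td / tau),
      start = list(p0 = max(min(fd), 0), amp = amp0, tau = span / 3),
      lower = c(p0 = 0, amp = 0, tau = 1e-9),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    fitted_peak <- cf[["p0"]] + cf[["amp"]]
    plateau <- if (fitted_peak > 0) unname(cf[["p0"]] / fitted_peak) else 1
    tau <- unname(cf[["tau"]])
    flat <- (1 - plateau) < flat_tol
    if (flat) tau <- NA_real_
  }
  out <- list(time_to_peak = time_to_peak, peak = peak,
              plateau = plateau, tau = tau, flat = flat)
  class(out) <- "response_fit"
  out
}
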