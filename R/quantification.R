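#' Relative surface expression from a two-fraction measurement
#'
#' Given the band (or smear) fluorescence intensity `S` of the surface
#' fraction loaded at dilution `1/a` and the intensity `I` of the
#' intracellular fraction at dilution `1/b`, the fraction of the protein at
#' the surface is `S / (S + b * I / a)`: the dilution correction `b/a` puts
#' both fractions back on the same amount scale before forming the ratio.
#'
#' @param m a `surface_fractions` measurement (see
#'   [simulate_surface_fractions()]), or `NULL` when `S`, `I`, `a`, `b` are
#'   given directly.
#' @param S,I,a,b band intensities and dilution parameters, used when `m` is
#'   `NULL`. Vectors are accepted and give a vector of ratios.
#' @return relative surface expression in \[0,1\].
#' @export
relative_surface_expression <- function(m = NULL, S, I, a = 1, b = 1) {
  if (!is.null(m)) {
    stopifnot(inherits(m, "surface_fractions"))
    S <- m$S; I <- m$I; a <- m$a; b <- m$b
  }
  if (any(a <= 0) || any(b <= 0))
    stop("dilution parameters a, b must be > 0", call. = FALSE)
  if (any(S < 0) || any(I < 0))
    stop("band intensities must be >= 0", call. = FALSE)
  denom <- S + b * I / a
  if (any(denom == 0))
    stop("undefined ratio: S and I are both zero", call. = FALSE)
  S / denom
}

#' Log2 treatment-to-control normalization
#'
#' Expresses each treated measurement relative to its paired control on the
#' log2 scale: 0 means no change, 1 a doubling, -1 a halving. With replicate
#' vectors per analyte the default forms the ratio of means over pairs
#' (`method = "ratio_of_means"`); `method = "mean_of_ratios"` averages the
#' per-pair log2 ratios instead.
#'
#' @param treated,control numeric vectors of paired measurements (same
#'   length); controls must be positive.
#' @param method aggregation across pairs when a single summary is wanted;
#'   `"none"` returns the per-pair log2 ratios.
#' @return log2 ratio(s).
#' @export
normalize_to_control <- function(treated, control,
                                 method = c("none", "ratio_of_means",
                                            "mean_of_ratios")) {
  method <- match.arg(method)
  if (length(treated) != length(control))
    stop("treated and control must be paired (equal length)", call. = FALSE)
  if (any(control <= 0))
    stop("undefined ratio: control values must be > 0", call. = FALSE)
  if (any(treated < 0))
    stop("treated values must be >= 0", call. = FALSE)
  switch(method,
         none = log2(treated / control),
         ratio_of_means = log2(mean(treated) / mean(control)),
         mean_of_ratios = mean(log2(treated / control)))
}
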