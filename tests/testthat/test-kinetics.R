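test_that("noise-free halving points give the exact half-life", {
  s <- data.frame(replicate = 1, time_h = c(0, 10, 20),
                  intensity = c(100, 50, 25))
  fit <- fit_half_life(s)
  expect_equal(fit$half_life, 10, tolerance = 1e-12)
  expect_equal(fit$lambda, log(2) / 10, tolerance = 1e-12)
  expect_false(fit$non_decaying)
})

test_that("a constant series is flagged as non-decaying, not an error", {
  s <- data.frame(replicate = 1, time_h = c(0, 5, 10, 20),
                  intensity = rep(80, 4))
  fit <- fit_half_life(s)
  expect_equal(fit$lambda, 0, tolerance = 1e-12)
  expect_true(fit$non_decaying)
  expect_equal(fit$half_life, Inf)
})

test_that("non-positive intensities are excluded with a count", {
  s <- data.frame(replicate = 1, time_h = c(0, 5, 10, 15, 20),
                  intensity = c(100, 50, 0, 12.5, 6.25))
  fit <- fit_half_life(s)
  expect_equal(fit$n_dropped, 1)
  expect_equal(fit$half_life, 5, tolerance = 1e-9)
  # too few positive points is an error
  s2 <- data.frame(replicate = 1, time_h = c(0, 5, 10),
                   intensity = c(100, 0, 0))
  expect_error(fit_half_life(s2), ">= 3 positive points")
})

test_that("the fit is scale invariant and time-covariant", {
  s <- simulate_decay_series(c(f = 7), times = c(0, 3, 6, 12, 24),
                             noise_cv = 0.05, seed = 17)
  f1 <- fit_half_life(s, form = "f")
  s2 <- s; s2$intensity <- s2$intensity * 1e3
  expect_equal(fit_half_life(s2, form = "f")$half_life, f1$half_life,
               tolerance = 1e-9)
  s3 <- s; s3$time_h <- s3$time_h * 4
  expect_equal(fit_half_life(s3, form = "f")$half_life, 4 * f1$half_life,
               tolerance = 1e-9)
})

test_that("per-replicate fits aggregate as mean with an SEM", {
  s <- simulate_decay_series(c(f = 10), times = c(0, 4, 8, 16, 24),
                             noise_cv = 0.1, n_rep = 4, seed = 19)
  fit <- fit_half_life(s, form = "f")
  expect_equal(nrow(fit$per_replicate), 4)
  expect_equal(fit$half_life, mean(fit$per_replicate$half_life))
  expect_equal(fit$sem, sd(fit$per_replicate$half_life) / 2)
})

test_that("glycoform comparison preserves constructed rate ratios", {
  times <- c(0, 2, 4, 8, 16)
  # identical series -> identical half-lives
  s_eq <- rbind(
    data.frame(replicate = 1, time_h = times, form = "core",
               intensity = 100 * 2^(-times / 6)),
    data.frame(replicate = 1, time_h = times, form = "mature",
               intensity = 100 * 2^(-times / 6)))
  cmp_eq <- compare_glycoform_turnover(s_eq)
  expect_equal(cmp_eq$half_lives[["core"]], cmp_eq$half_lives[["mature"]],
               tolerance = 1e-10)
  # planted 3x faster core decay, noise-free -> exact 3x rate ratio
  s3 <- rbind(
    data.frame(replicate = 1, time_h = times, form = "core",
               intensity = 100 * 2^(-times / 4)),
    data.frame(replicate = 1, time_h = times, form = "mature",
               intensity = 100 * 2^(-times / 12)))
  cmp3 <- compare_glycoform_turnover(s3)
  expect_equal(cmp3$lambda_ratio_core_mature, 3, tolerance = 1e-10)
  expect_true(cmp3$core_faster)
  # a summed total decays between its two components
  s_tot <- simulate_decay_series(c(core = 3.4, mature = 21.1),
                                 times = c(0, 2, 4, 8, 16, 24),
                                 noise_cv = 0, include_total = TRUE)
  cmp_tot <- compare_glycoform_turnover(s_tot)
  expect_gt(cmp_tot$half_lives[["total"]], cmp_tot$half_lives[["core"]])
  expect_lt(cmp_tot$half_lives[["total"]], cmp_tot$half_lives[["mature"]])
  # a missing form yields a flagged partial result
  expect_warning(cmp_part <- compare_glycoform_turnover(
    s_tot[s_tot$form != "mature", ]), "mature")
  expect_equal(cmp_part$missing_forms, "mature")
  expect_true(is.na(cmp_part$core_faster))
})

# noise-free model trace: linear rise to the peak, then plateau decay
model_trace <- function(plateau, tau, t_peak = 1, t_end = 11, dt = 0.05) {
  t <- seq(0, t_end, by = dt)
  f <- ifelse(t < t_peak, t / t_peak,
              plateau + (1 - plateau) * exp(-(t - t_peak) / tau))
  list(t = t, f = f)
}

test_that("response kinetics recover exact model parameters", {
  tr <- model_trace(plateau = 0.4, tau = 2)
  fit <- response_kinetics(tr$t, tr$f, onset = 0)
  expect_equal(fit$time_to_peak, 1, tolerance = 1e-9)
  expect_equal(fit$peak, 1, tolerance = 1e-9)
  expect_equal(fit$plateau, 0.4, tolerance = 1e-6)
  expect_equal(fit$tau, 2, tolerance = 1e-6)
  expect_false(fit$flat)
})

test_that("a non-decaying response leaves tau unidentifiable", {
  tr <- model_trace(plateau = 1, tau = 2)
  fit <- response_kinetics(tr$t, tr$f, onset = 0)
  expect_true(fit$flat)
  expect_true(is.na(fit$tau))
  # monotone rising trace has no peak
  t <- seq(0, 5, 0.1)
  expect_error(response_kinetics(t, t, onset = 0), "no peak")
})

test_that("noisy traces recover tau and plateau within 10%", {
  set.seed(61)
  taus <- plateaus <- numeric(100)
  for (i in 1:100) {
    tr <- model_trace(plateau = 0.4, tau = 2)
    f <- tr$f * exp(rnorm(length(tr$f), 0, 0.05))
    fit <- response_kinetics(tr$t, f, onset = 0)
    taus[i] <- fit$tau; plateaus[i] <- fit$plateau
  }
  expect_lt(abs(median(taus) - 2) / 2, 0.10)
  expect_lt(abs(median(plateaus) - 0.4) / 0.4, 0.10)
})
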