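test_that("a fixed seed makes the simulated table bit-identical", {
  cfg <- sim_config(n_proteins = 40, seed = 7)
  sim1 <- simulate_peptide_table(cfg)
  sim2 <- simulate_peptide_table(cfg)
  expect_identical(sim1$table$intensities, sim2$table$intensities)
  expect_identical(sim1$table$design, sim2$table$design)
  expect_identical(sim1$truth, sim2$truth)
})

test_that("the default design reproduces 14 runs per condition", {
  sim <- simulate_peptide_table(sim_config(n_proteins = 5, seed = 1))
  counts <- table(sim$table$design$condition)
  expect_equal(unname(counts[["A"]]), 14)
  expect_equal(unname(counts[["B"]]), 14)
  # 2 biological x 2 experimental preparations, 3-4 injections each
  a <- sim$table$design[sim$table$design$condition == "A", ]
  expect_equal(as.integer(sort(table(a$prep))), c(3L, 3L, 4L, 4L))
})

test_that("zero variance components give identical runs within condition", {
  cfg <- sim_config(n_proteins = 20, sigma_bio = 0, sigma_exp = 0,
                    sigma_tech = 0, dropout_B = 0, seed = 3)
  sim <- simulate_peptide_table(cfg)
  m <- sim$table$intensities
  for (cond in c("A", "B")) {
    sub <- m[, sim$table$design$condition == cond, drop = FALSE]
    expect_true(all(apply(sub, 1, function(x) diff(range(x)) == 0)))
  }
  # target peptides attenuated by exactly the configured factor in B
  tgt <- sim$truth$peptides$is_target
  a_mean <- rowMeans(m[, sim$table$design$condition == "A"])
  b_mean <- rowMeans(m[, sim$table$design$condition == "B"])
  expect_equal(unname(a_mean[tgt] / b_mean[tgt]),
               rep(cfg$target_B_attenuation, sum(tgt)), tolerance = 1e-12)
  expect_equal(unname(a_mean[!tgt]), unname(b_mean[!tgt]),
               tolerance = 1e-12)
})

test_that("B-condition dropout hits the configured rate (binomial check)", {
  # ~10^4 target-peptide x B-run cells
  cfg <- sim_config(n_proteins = 715, frac_target = 1,
                    peptides_per_protein = 1, dropout_B = 0.6, seed = 11)
  sim <- simulate_peptide_table(cfg)
  b_cells <- sim$table$intensities[, sim$table$design$condition == "B"]
  n <- length(b_cells)
  frac_missing <- mean(is.na(b_cells))
  expect_gt(n, 9000)
  expect_lt(abs(frac_missing - 0.6), 3 * sqrt(0.6 * 0.4 / n))
})

test_that("invalid configuration errors name the offending field", {
  expect_error(sim_config(n_proteins = 0), "n_proteins")
  expect_error(sim_config(frac_target = 1.2), "frac_target")
  expect_error(sim_config(sigma_bio = -1), "sigma_bio")
  expect_error(sim_config(dropout_B = -0.1), "dropout_B")
  expect_error(sim_config(target_B_attenuation = 0), "target_B_attenuation")
})

test_that("simulated log intensities recover the biological ICC target", {
  # many biological replicates so the per-peptide ICC estimate is stable
  cfg <- sim_config(n_proteins = 500, frac_target = 0,
                    peptides_per_protein = 2, n_bio = 8, n_exp = 2,
                    n_tech = 2, sigma_bio = 0.5, sigma_exp = 0.3,
                    sigma_tech = 0.2, dropout_B = 0,
                    background_noise_inflation = 1, seed = 5)
  sim <- simulate_peptide_table(cfg)
  a_runs <- sim$table$design$condition == "A"
  bio <- sim$table$design$bio_rep[a_runs]
  logm <- log(sim$table$intensities[, a_runs])
  icc <- apply(logm, 1, icc_oneway, classes = bio)
  truth <- 0.5^2 / (0.5^2 + 0.3^2 + 0.2^2)
  expect_lt(abs(mean(icc) - truth), 0.05)
})

test_that("decay series follow exact halving without noise", {
  s <- simulate_decay_series(c(total = 10), times = c(0, 10, 20),
                             noise_cv = 0, I0 = 100)
  expect_equal(s$intensity, c(100, 50, 25))
  expect_error(simulate_decay_series(c(x = -1), times = 0:2), "positive")
  expect_error(simulate_decay_series(c(x = 1), times = c(2, 1)), "sorted")
})

test_that("the fast glycoform lies below the slow one at every t > 0", {
  s <- simulate_decay_series(c(core = 3.4, mature = 21.1),
                             times = c(0, 2, 4, 8, 16, 24), noise_cv = 0)
  core <- s$intensity[s$form == "core"]
  mature <- s$intensity[s$form == "mature"]
  expect_equal(core[1], mature[1])
  expect_true(all(core[-1] < mature[-1]))
  # fixed seed reproducibility with noise
  s1 <- simulate_decay_series(c(core = 3.4), times = 0:5, noise_cv = 0.2,
                              seed = 9)
  s2 <- simulate_decay_series(c(core = 3.4), times = 0:5, noise_cv = 0.2,
                              seed = 9)
  expect_identical(s1, s2)
})

test_that("surface-fraction simulation is unbiased around the true ratio", {
  expect_equal(simulate_surface_fractions(1, seed = 1)$I, 0)
  m <- simulate_surface_fractions(0.5, a = 2, b = 2, seed = 1)
  expect_equal(m$S, m$I)
  est <- vapply(1:500, function(s) {
    relative_surface_expression(
      simulate_surface_fractions(0.3, a = 2, b = 5, noise_cv = 0.1,
                                 seed = s))
  }, 1)
  expect_lt(abs(mean(est) - 0.3), 2 * sd(est) / sqrt(length(est)))
  expect_error(simulate_surface_fractions(1.5), "\\[0,1\\]")
})
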