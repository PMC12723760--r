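# Shared preset for this file (membership derivation is the slow part).
preset <- preset_a4learn_like()

test_that("same seed reproduces the cohort exactly; different seed differs", {
  s1 <- simulate_cohort(preset, n = 120, seed = 5)
  s2 <- simulate_cohort(preset, n = 120, seed = 5)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$true_class, s2$true_class)
  s3 <- simulate_cohort(preset, n = 120, seed = 6)
  expect_false(identical(s1$cohort$visits$pacc, s3$cohort$visits$pacc))
})

test_that("noise-free single-class cohort lies exactly on the mean curve", {
  truth <- make_simple_truth(sigma_b = 0, sigma_e = 0, n = 30)
  sim <- simulate_cohort(truth, seed = 3)
  v <- sim$cohort$visits
  expected <- as.vector(cbind(1, eval_spline_basis(truth$basis,
                                                   v$time_years)) %*%
                          t(truth$alpha))
  expect_equal(v$pacc, expected, tolerance = 1e-12)
})

test_that("generator rejects invalid truths", {
  expect_error(simulation_truth(
    10, mixing = 1, alpha = matrix(1, 1, 2),
    basis = build_spline_basis(c(0, 3), 1), zeta = matrix(0, 0, 1),
    gamma = numeric(0), covariate_centers = numeric(0),
    covariates = list(), sigma_b = 1, sigma_e = 1,
    boxcox = structure(list(lambda = 1, shift = 1),
                       class = "boxcox_transform"),
    visit_schedule = c(1, 2), dropout_hazard = 0), "start at 0")
  expect_error(simulation_truth(
    10, mixing = c(0.6, 0.6), alpha = matrix(1, 2, 2),
    basis = build_spline_basis(c(0, 3), 1), zeta = matrix(0, 1, 1),
    gamma = numeric(0), covariate_centers = numeric(0),
    covariates = list(), sigma_b = 1, sigma_e = 1,
    boxcox = structure(list(lambda = 1, shift = 1),
                       class = "boxcox_transform"),
    visit_schedule = c(0, 2), dropout_hazard = 0), "sum to 1")
})

test_that("dropout is monotone: retained visits are a prefix of the schedule", {
  sim <- simulate_cohort(preset, n = 400, seed = 9)
  sched <- preset$visit_schedule
  by_subj <- split(sim$cohort$visits$time_years,
                   sim$cohort$visits$subject_id)
  expect_true(all(vapply(by_subj, function(tt)
    identical(unname(tt), sched[seq_along(tt)]), logical(1))))
})

test_that("empirical class frequencies match the marginalized logit oracle", {
  # oracle: Monte-Carlo marginalization of the multinomial-logit membership
  # probabilities over the covariate mixture
  set.seed(123)
  comp <- sample.int(3, 40000, replace = TRUE, prob = preset$mixing)
  cov <- cogmix:::draw_covariates(preset, comp)
  target <- colMeans(cogmix:::truth_class_probs(preset, cov))
  expect_lt(max(abs(target - preset$mixing)), 0.02)

  sim <- simulate_cohort(preset, n = 4000, seed = 21)
  freq <- as.vector(table(factor(sim$true_class, 1:3))) / 4000
  expect_lt(max(abs(freq - target)), 0.02)
})

test_that("simulated covariate moments converge to the generating values", {
  sim <- simulate_cohort(preset, n = 30000, seed = 31)
  b <- sim$cohort$baseline
  cls <- sim$true_class[b$subject_id]
  for (g in 1:3) {
    n_g <- sum(cls == g)
    # unbounded normal components: sample mean within 3 MC SEs
    for (nm in c("age", "education")) {
      d <- preset$covariates$normal[[nm]]
      se <- d$sd[g] / sqrt(n_g)
      expect_lt(abs(mean(b[[nm]][cls == g]) - d$mean[g]), 3 * se + 1e-9,
                label = sprintf("%s mean, class %d", nm, g))
    }
    # bernoulli components
    for (nm in c("sex_female", "apoe4_carrier")) {
      p <- preset$covariates$bernoulli[[nm]][g]
      se <- sqrt(p * (1 - p) / n_g)
      expect_lt(abs(mean(b[[nm]][cls == g]) - p), 3 * se + 1e-9,
                label = sprintf("%s rate, class %d", nm, g))
    }
  }
  # atrophy z-score recovered through the constructed volume/ICV pair
  # z is re-standardized over the realized sample, so class means match the
  # generating values up to the overall location/scale (near 0/1 here)
  z <- residualize_and_z(b$hippocampal_volume, b$icv)
  zt <- tapply(z, cls, mean)
  want <- preset$covariates$normal$hipp_atrophy_z$mean
  expect_lt(max(abs(zt - want)), 0.25)
})

test_that("marginal outcome variance equals sigma_b^2 + sigma_e^2", {
  truth <- make_simple_truth(sigma_b = 1.5, sigma_e = 0.8, n = 30000,
                             schedule = c(0, 1))
  sim <- simulate_cohort(truth, seed = 13)
  v <- sim$cohort$visits
  z0 <- apply_boxcox(truth$boxcox, v$pacc[v$time_years == 0])
  target <- truth$sigma_b^2 + truth$sigma_e^2
  mc_se <- target * sqrt(2 / length(z0))
  expect_lt(abs(var(z0) - target), 3 * mc_se)
})

test_that("preset anchors match the published trajectory and mixing values", {
  Sg <- cbind(1, eval_spline_basis(preset$basis, c(0, 6)))
  curves <- unname(Sg %*% t(preset$alpha))  # identity transform: PACC scale
  expect_equal(curves[2, 1], 1.16, tolerance = 1e-8)   # stable at 6 y
  expect_equal(curves[1, 3], -0.98, tolerance = 1e-8)  # fast at baseline
  expect_equal(curves[2, 3], -15.8, tolerance = 1e-8)  # fast at 6 y
  expect_equal(curves[1, 2], -0.13, tolerance = 1e-8)  # slow at baseline
  expect_equal(unname(preset$mixing), c(0.77, 0.16, 0.07))
  expect_equal(inverse_boxcox(preset$boxcox,
                              apply_boxcox(preset$boxcox, c(-15, 0, 2))),
               c(-15, 0, 2))
})

test_that("tau PET is acquired in a subset and the tau model uses only it", {
  sim <- simulate_cohort(preset, n = 1500, seed = 91)
  b <- sim$cohort$baseline
  miss <- mean(is.na(b$tau_pet_composite))
  expect_gt(miss, 0.65); expect_lt(miss, 0.85)
  spec_tau <- lcmm_spec(
    G = 3, spline_df = 2,
    longitudinal_covariates = c(cogmix:::default_longitudinal_covariates,
                                "tau_pet_composite"),
    membership_covariates = setdiff(
      c(cogmix:::default_longitudinal_covariates, "tau_pet_composite"),
      "pacc_version"))
  ld <- prepare_lcmm_data(sim$cohort, spec_tau, transform = preset$boxcox)
  expect_equal(ld$n_subjects, sum(!is.na(b$tau_pet_composite)))
  expect_true("tau_pet_composite" %in% colnames(ld$X))
})

test_that("truth serializes to JSON", {
  p <- withr::local_tempfile(fileext = ".json")
  truth_to_json(preset, p)
  rec <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(rec$sigma_b, preset$sigma_b)
  expect_equal(unname(unlist(rec$mixing)), unname(unlist(preset$mixing)))
})
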