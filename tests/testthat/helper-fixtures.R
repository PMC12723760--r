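# Shared fixtures and independent oracles, built in code.

# Small random cohort with all required columns.
make_toy_cohort <- function(n_subjects = 6, n_visits = 4, seed = 1) {
  set.seed(seed)
  ids <- sprintf("T%03d", seq_len(n_subjects))
  visits <- do.call(rbind, lapply(ids, function(id) {
    tt <- sort(c(0, runif(n_visits - 1, 0.3, 6)))
    data.frame(subject_id = id, time_years = tt,
               pacc = rnorm(n_visits, 0, 2),
               pacc_version = rep_len(1:2, n_visits),
               cdr_global = sample(c(0, 0, 0, 0.5), n_visits, replace = TRUE),
               cdr_memory = 0,
               amyloid_centiloid = rnorm(n_visits, 40, 5),
               ptau217 = runif(n_visits, 0.1, 0.5),
               tau_mtl_suvr = NA_real_, tau_neo_suvr = NA_real_,
               hippocampal_volume = rnorm(n_visits, 7000, 100))
  }))
  baseline <- data.frame(
    subject_id = ids,
    arm = sample(c("LEARN", "placebo", "solanezumab"), n_subjects, TRUE),
    ptau217 = runif(n_subjects, 0.1, 0.5),
    amyloid_suvr = runif(n_subjects, 1.0, 1.6),
    amyloid_centiloid = rnorm(n_subjects, 45, 30),
    apoe4_carrier = rbinom(n_subjects, 1, 0.5),
    sex_female = rbinom(n_subjects, 1, 0.6),
    age = rnorm(n_subjects, 71, 4),
    education = rnorm(n_subjects, 16, 3),
    hippocampal_volume = rnorm(n_subjects, 7200, 300),
    icv = rnorm(n_subjects, 1.45e6, 1e5),
    tau_pet_composite = NA_real_)
  cohort_data(visits, baseline)
}

# Brute-force mixture log-likelihood: explicit dense multivariate-normal
# densities with solve()/det(), summed on the probability scale. Independent
# of the package's pattern-grouped log-sum-exp implementation.
oracle_loglik <- function(ldata, alpha, gamma, sigma_b, sigma_e, zeta = NULL) {
  alpha <- rbind(alpha)
  G <- nrow(alpha)
  ll <- 0
  for (i in seq_len(ldata$n_subjects)) {
    rows <- which(ldata$obs_subject == i)
    k <- length(rows)
    V <- matrix(sigma_b^2, k, k) + diag(sigma_e^2, k)
    Vi <- solve(V)
    wg <- if (length(gamma)) cogmix:::w_gamma(ldata, gamma)[rows] else 0
    pi_g <- if (G == 1) 1
      else if (is.null(zeta)) rep(1 / G, G)
      else {
        eta <- c(0, as.vector(ldata$X[i, ] %*% t(zeta)))
        exp(eta) / sum(exp(eta))
      }
    logdens <- vapply(seq_len(G), function(g) {
      r <- ldata$z[rows] - (ldata$S[rows, , drop = FALSE] %*% alpha[g, ] + wg)
      -k / 2 * log(2 * pi) - 0.5 * log(det(V)) -
        0.5 * as.numeric(t(r) %*% Vi %*% r)
    }, numeric(1))
    m0 <- max(logdens)
    ll <- ll + m0 + log(sum(pi_g * exp(logdens - m0)))
  }
  ll
}

# Prepared data for a toy cohort with a fixed transform and no covariates,
# convenient for likelihood oracles.
make_toy_ldata <- function(n_subjects = 4, n_visits = 3, seed = 2,
                           with_covariates = FALSE) {
  cohort <- make_toy_cohort(n_subjects, n_visits, seed)
  covs <- if (with_covariates) c("ptau217", "age") else character(0)
  spec <- lcmm_spec(G = 2, spline_df = 1,
                    longitudinal_covariates = covs,
                    membership_covariates = covs,
                    standardize = FALSE)
  tf <- structure(list(lambda = 1, shift = 1), class = "boxcox_transform")
  prepare_lcmm_data(cohort, spec, transform = tf)
}

# Natural cubic spline oracle: truncated-power construction of the natural
# spline space on knots (b0, interior..., b1) — functions linear beyond the
# boundary knots. Returns the non-intercept basis (dimension = n_knots - 1).
truncated_power_natural_basis <- function(times, knots) {
  K <- length(knots)
  d <- function(t, j)
    (pmax(t - knots[j], 0)^3 - pmax(t - knots[K], 0)^3) / (knots[K] - knots[j])
  cols <- list(t = times)
  if (K > 2) for (j in seq_len(K - 2))
    cols[[paste0("n", j)]] <- d(times, j) - d(times, K - 1)
  do.call(cbind, cols)
}

# Minimal one-class truth for generator property tests.
make_simple_truth <- function(sigma_b = 0, sigma_e = 0, n = 50,
                              schedule = c(0, 1, 2, 3), dropout = 0,
                              gamma0 = TRUE) {
  basis <- build_spline_basis(range(schedule), 1)
  alpha <- matrix(c(1, -3), 1, 2)   # start 1, decline
  tf <- structure(list(lambda = 1, shift = 1), class = "boxcox_transform")
  simulation_truth(
    n_subjects = n, mixing = 1, alpha = alpha, basis = basis,
    zeta = matrix(0, 0, 1),
    gamma = c(sex_female = if (gamma0) 0 else 0.5),
    covariate_centers = c(sex_female = 0.5),
    covariates = list(normal = list(), bernoulli = list(sex_female = 0.5)),
    sigma_b = sigma_b, sigma_e = sigma_e, boxcox = tf,
    visit_schedule = schedule, dropout_hazard = dropout,
    cdr_progression_prob = 0.2, seed = 7)
}

# Single-class variant of the preset (stable-class covariate marginals),
# used for the G = 1 null specificity battery.
make_null_truth <- function() {
  p <- preset_a4learn_like(derive_n = 200)  # zeta unused for G = 1
  cv <- p$covariates
  take1 <- function(d) lapply(d, function(x) if (length(x) == 3) x[1] else x)
  simulation_truth(
    n_subjects = 1000, mixing = 1,
    alpha = p$alpha[1, , drop = FALSE], basis = p$basis,
    zeta = matrix(0, 0, 1), gamma = p$gamma,
    covariate_centers = p$covariate_centers,
    covariates = list(
      normal = lapply(cv$normal, take1),
      bernoulli = lapply(cv$bernoulli, function(x) x[1]),
      arm = cv$arm[1, , drop = FALSE]),
    sigma_b = p$sigma_b, sigma_e = p$sigma_e, boxcox = p$boxcox,
    visit_schedule = p$visit_schedule, dropout_hazard = p$dropout_hazard[1],
    cdr_progression_prob = p$cdr_progression_prob[1], seed = 11)
}

expect_monotone_trace <- function(fit) {
  tr <- fit$loglik_trace
  expect_true(all(diff(tr) >= -1e-9 * (1 + abs(tr[-1]))),
              label = "EM log-likelihood trace is non-decreasing")
}
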