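# Synthetic cohort generator. Produces cohorts with exactly the statistical
# structure the latent class mixed model assumes — multinomial-logit class
# membership given baseline covariates, class-specific spline mean
# trajectories on a transformed scale, subject random intercepts, Gaussian
# residuals, semiannual-then-annual visits and monotone dropout — so every
# downstream stage can be tested against known ground truth.

#' Construct a simulation truth object
#'
#' Houses the generative counterparts of every model parameter. Class-mean
#' trajectories are parameterized by natural-spline coefficients
#' \code{alpha} on the transformed outcome scale; \code{zeta} drives a
#' multinomial-logit membership model on the raw-scale covariates, so
#' simulated data satisfy the estimator's membership assumption exactly.
#'
#' @param n_subjects Default cohort size.
#' @param mixing Marginal probabilities of the covariate mixture components
#'   (one per class); the realized class is drawn from the logit model, whose
#'   marginal matches \code{mixing} by construction.
#' @param alpha G x (1 + spline_df) matrix of class trajectory coefficients
#'   for the basis defined by \code{basis}.
#' @param basis A \code{spline_basis} for the trajectory curves.
#' @param zeta (G-1) x (1 + p) membership coefficients on raw covariates
#'   (reference class 1), columns named.
#' @param gamma Named shared covariate effects (raw scale, applied to
#'   centered covariates).
#' @param covariate_centers Named population means used to center covariates
#'   in the longitudinal predictor (keeps class curves anchored at the
#'   mean-covariate profile).
#' @param covariates Per-class covariate distribution list (see
#'   [preset_a4learn_like()] for the expected layout).
#' @param sigma_b,sigma_e Random-intercept and residual SDs (transformed
#'   scale).
#' @param boxcox Transform linking the model scale to the observed scale
#'   (a \code{boxcox_transform}).
#' @param visit_schedule Nominal visit times in years, starting at 0,
#'   strictly increasing.
#' @param dropout_hazard Per-interval dropout probability, scalar or one per
#'   class.
#' @param cdr_progression_prob Per-class probability of CDR progression.
#' @param biomarker_slopes Per-class yearly drift of longitudinal biomarkers
#'   (list of named vectors).
#' @param seed Default seed.
#' @return An object of class \code{simulation_truth}.
#' @export
simulation_truth <- function(n_subjects, mixing, alpha, basis, zeta, gamma,
                             covariate_centers, covariates, sigma_b, sigma_e,
                             boxcox, visit_schedule, dropout_hazard,
                             cdr_progression_prob = NULL,
                             biomarker_slopes = NULL, seed = 1L) {
  G <- length(mixing)
  if (G < 1) stopf("at least one class required")
  if (!length(visit_schedule) || visit_schedule[1] != 0 ||
      any(diff(visit_schedule) <= 0))
    stopf("visit_schedule must start at 0 and be strictly increasing")
  if (sigma_b < 0 || sigma_e < 0) stopf("SDs must be non-negative")
  dh <- rep(dropout_hazard, length.out = G)
  if (any(dh < 0 | dh >= 1)) stopf("dropout hazard must be in [0, 1)")
  if (abs(sum(mixing) - 1) > 1e-8) stopf("mixing must sum to 1")
  structure(list(
    n_subjects = n_subjects, G = G, mixing = mixing,
    alpha = rbind(alpha), basis = basis, zeta = zeta, gamma = gamma,
    covariate_centers = covariate_centers, covariates = covariates,
    sigma_b = sigma_b, sigma_e = sigma_e, boxcox = boxcox,
    visit_schedule = visit_schedule, dropout_hazard = dh,
    cdr_progression_prob = cdr_progression_prob %||% rep(0, G),
    biomarker_slopes = biomarker_slopes, seed = as.integer(seed)
  ), class = "simulation_truth")
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

# Draw class-conditional baseline covariates for component assignment comp.
draw_covariates <- function(truth, comp) {
  n <- length(comp)
  cv <- truth$covariates
  pick <- function(v) v[comp]
  out <- data.frame(row.names = seq_len(n))
  for (nm in names(cv$normal)) {
    d <- cv$normal[[nm]]
    out[[nm]] <- rnorm_trunc(n, pick(d$mean), pick(d$sd),
                             d$lower %||% -Inf, d$upper %||% Inf)
  }
  for (nm in names(cv$bernoulli))
    out[[nm]] <- stats::rbinom(n, 1, pick(cv$bernoulli[[nm]]))
  if (!is.null(cv$arm)) {
    out$arm <- vapply(comp, function(g)
      sample(arm_levels, 1, prob = cv$arm[g, ]), character(1))
    out$active_treatment <- as.integer(out$arm == "solanezumab")
  }
  if ("amyloid_centiloid" %in% names(out))
    out$amyloid_suvr <- 1.01 + out$amyloid_centiloid / 183
  out
}

# Multinomial-logit class probabilities on raw covariates.
truth_class_probs <- function(truth, cov) {
  if (truth$G == 1L) return(matrix(1, nrow(cov), 1))
  X <- cbind(1, as.matrix(cov[, colnames(truth$zeta)[-1], drop = FALSE]))
  eta <- cbind(0, X %*% t(truth$zeta))
  exp(eta - logsumexp_rows(eta))
}

#' Simulate a cohort from a simulation truth
#'
#' Per subject: draw a covariate mixture component and its covariates; draw
#' the latent class from the multinomial-logit membership model on those
#' covariates; draw a random intercept; generate transformed-scale outcomes
#' at retained visits (class spline mean + centered shared covariate effects
#' + intercept + residual); back-transform to the observed scale; apply
#' monotone dropout after each visit; and simulate CDR progression with the
#' class-specific probability (progression realized as CDR 0.5 from a random
#' onset visit onward).
#'
#' @param truth A \code{simulation_truth}.
#' @param n Number of subjects (default \code{truth$n_subjects}).
#' @param seed Integer seed (default \code{truth$seed}).
#' @return List with \code{cohort} (a \code{cohort_data}), \code{true_class}
#'   (named integer vector) and \code{truth}.
#' @export
simulate_cohort <- function(truth, n = truth$n_subjects, seed = truth$seed) {
  stopifnot(inherits(truth, "simulation_truth"))
  set.seed(seed)
  G <- truth$G
  ids <- sprintf("SIM%05d", seq_len(n))

  comp <- sample.int(G, n, replace = TRUE, prob = truth$mixing)
  cov <- draw_covariates(truth, comp)
  probs <- truth_class_probs(truth, cov)
  if (G == 1L) {
    cls <- rep(1L, n)
  } else {
    u <- stats::runif(n)
    cum <- t(apply(probs, 1, cumsum))
    cls <- rowSums(u > cum) + 1L
  }


  # retained visits: monotone dropout with per-class hazard after each visit
  sched <- truth$visit_schedule
  nv <- length(sched)
  haz <- truth$dropout_hazard[cls]
  n_ret <- rep(nv, n)
  if (any(haz > 0)) {
    gq <- stats::rgeom(n, pmax(haz, 1e-12)) + 1L  # visits survived
    n_ret <- pmin(ifelse(haz > 0, gq, nv), nv)
  }

  b_i <- stats::rnorm(n, 0, truth$sigma_b)
  Sg <- cbind(1, eval_spline_basis(truth$basis, sched))
  curves <- Sg %*% t(truth$alpha)                       # nv x G

  gnames <- names(truth$gamma)
  wc <- as.matrix(cov[, gnames[gnames %in% names(cov)], drop = FALSE])
  centers <- truth$covariate_centers[colnames(wc)]
  woff <- as.vector((wc - matrix(centers, n, ncol(wc), byrow = TRUE)) %*%
                      truth$gamma[colnames(wc)])

  visits <- vector("list", n)
  prog <- stats::rbinom(n, 1, truth$cdr_progression_prob[cls])
  for (i in seq_len(n)) {
    k <- n_ret[i]
    t_i <- sched[seq_len(k)]
    version <- rep_len(c(1L, 2L), k)
    z <- curves[seq_len(k), cls[i]] + woff[i] +
      if ("pacc_version" %in% gnames)
        truth$gamma[["pacc_version"]] * (version - 1.5) else 0
    z <- z + b_i[i] + stats::rnorm(k, 0, truth$sigma_e)
    y <- inverse_boxcox(truth$boxcox, z)
    cdr <- rep(0, k)
    if (prog[i] == 1 && k >= 2) {
      onset <- sample(2:k, 1)
      cdr[onset:k] <- 0.5
    }
    visits[[i]] <- data.frame(
      subject_id = ids[i], time_years = t_i, pacc = y,
      pacc_version = version, cdr_global = cdr, cdr_memory = cdr)
  }
  v <- do.call(rbind, visits)

  v <- add_longitudinal_biomarkers(v, truth, cov, cls, ids)
  b <- build_baseline_table(truth, cov, ids)

  # class-specific missingness of the tau PET composite (acquired only in a
  # study subset); drawn last so the remainder of the cohort is unaffected
  tm <- truth$covariates$tau_missing
  if (!is.null(tm) && !all(is.na(b$tau_pet_composite)))
    b$tau_pet_composite[stats::runif(n) < tm[cls]] <- NA_real_

  cohort <- cohort_data(v, b)
  true_class <- stats::setNames(cls, ids)
  list(cohort = cohort, true_class = true_class, truth = truth)
}

# Baseline table: construct hippocampal volume and ICV so that
# residualize_and_z() recovers the target atrophy z-score (volume decreases
# with atrophy, increases with head size).
build_baseline_table <- function(truth, cov, ids) {
  n <- nrow(cov)
  icv <- stats::rnorm(n, 1.45e6, 1.4e5)
  zt <- if ("hipp_atrophy_z" %in% names(cov)) cov$hipp_atrophy_z else
    stats::rnorm(n)
  volume <- 7500 + 0.002 * (icv - 1.45e6) - 350 * zt
  suvr <- cov$amyloid_suvr %||% stats::rnorm(n, 1.1, 0.2)
  data.frame(
    subject_id = ids,
    arm = cov$arm %||% rep("placebo", n),
    ptau217 = cov$ptau217 %||% NA_real_,
    amyloid_suvr = suvr,
    amyloid_centiloid = cov$amyloid_centiloid %||% NA_real_,
    apoe4_carrier = cov$apoe4_carrier %||% NA_integer_,
    sex_female = cov$sex_female %||% NA_integer_,
    age = cov$age %||% NA_real_,
    education = cov$education %||% NA_real_,
    hippocampal_volume = volume, icv = icv,
    tau_pet_composite = cov$tau_pet_composite %||% NA_real_)
}

# Longitudinal biomarker values at retained visits: baseline level plus a
# class-specific yearly drift, a subject random slope, and measurement noise.
add_longitudinal_biomarkers <- function(v, truth, cov, cls, ids) {
  if (is.null(truth$biomarker_slopes)) {
    return(v)
  }
  sid <- match(v$subject_id, ids)
  t_obs <- v$time_years
  bs <- truth$biomarker_slopes
  base_map <- list(amyloid_centiloid = "amyloid_centiloid",
                   ptau217 = "ptau217")
  for (nm in names(bs$slope)) {
    slope <- bs$slope[[nm]][cls] +
      stats::rnorm(length(ids), 0, bs$slope_sd %||% 0)
    base <- if (!is.null(base_map[[nm]]) && base_map[[nm]] %in% names(cov))
      cov[[base_map[[nm]]]] else rep(bs$baseline[[nm]] %||% 0, length(ids))
    noise_sd <- bs$noise_sd[[nm]] %||% 0
    v[[nm]] <- base[sid] + slope[sid] * t_obs +
      stats::rnorm(length(t_obs), 0, noise_sd)
  }
  v
}

#' Ready-made truth emulating a large preclinical AD cohort
#'
#' A three-class truth (stable 77\%, slow decliner 16\%, fast decliner 7\%)
#' whose class-conditional covariate profiles and 6-year class mean
#' trajectories match published summaries for the combined A4/LEARN design:
#' class mean PACC of 0.52 at baseline rising to 1.16 at 6 years (stable),
#' -0.13 falling to -4.74 (slow decliner), and -0.98 falling to -15.8 (fast
#' decliner). Interior anchor values at 3 years are an interpolation choice
#' (mildly accelerating decline; early practice-effect gain for the stable
#' class). The transform linking model and observed scale is the identity
#' member of the Box-Cox family, so the anchors are exact on both scales.
#' The membership coefficients are derived, once and deterministically, by
#' fitting a multinomial logit to a large internal draw from the
#' class-conditional covariate mixture — simulated cohorts therefore satisfy
#' the estimator's membership assumption exactly.
#'
#' @param n_subjects Default cohort size (1629, the published analytic
#'   sample).
#' @param derive_n,derive_seed Size and seed of the internal draw used to
#'   derive the membership coefficients.
#' @return A \code{simulation_truth}.
#' @export
preset_a4learn_like <- function(n_subjects = 1629, derive_n = 20000,
                                derive_seed = 20260121) {
  mixing <- c(stable = 0.77, slow = 0.16, fast = 0.07)
  covariates <- list(
    normal = list(
      ptau217 = list(mean = c(0.20, 0.33, 0.45), sd = c(0.09, 0.16, 0.26),
                     lower = 0.01),
      amyloid_centiloid = list(mean = c(37.4, 72.1, 88.6),
                               sd = c(34.8, 42.9, 37.8)),
      age = list(mean = c(70.78, 74.06, 73.10), sd = c(4.29, 5.24, 5.12)),
      education = list(mean = c(16.62, 16.58, 16.32),
                       sd = c(2.74, 2.70, 2.85)),
      hipp_atrophy_z = list(mean = c(-0.20, 0.60, 0.95),
                            sd = c(0.96, 0.96, 0.87)),
      tau_pet_composite = list(mean = c(1.08, 1.13, 1.23),
                               sd = c(0.07, 0.08, 0.13), lower = 0.8)
    ),
    bernoulli = list(
      sex_female = c(0.607, 0.538, 0.689),
      apoe4_carrier = c(0.418, 0.632, 0.739)
    ),
    # fraction without tau PET, by class (tau imaging in a subset only)
    tau_missing = c(0.75, 0.71, 0.65),
    arm = rbind(stable = c(0.383, 0.307, 0.310),
                slow = c(0.138, 0.506, 0.356),
                fast = c(0.025, 0.412, 0.563))
  )

  basis <- build_spline_basis(c(0, 2.5, 7), 2)  # boundary 0/7, knot 2.5 y
  anchors_t <- c(0, 3, 6)
  anchors <- rbind(stable = c(0.52, 0.95, 1.16),
                   slow = c(-0.13, -1.70, -4.74),
                   fast = c(-0.98, -6.30, -15.80))
  M <- cbind(1, eval_spline_basis(basis, anchors_t))
  alpha <- t(solve(M, t(anchors)))

  # shared covariate effects (observed-scale points per raw unit); centered
  # at the population means so class curves hold at the mean profile
  gamma <- c(active_treatment = 0, ptau217 = -0.4, amyloid_suvr = 0,
             apoe4_carrier = -0.05, sex_female = 0.30,
             age = -0.03, education = 0.044, hipp_atrophy_z = -0.10,
             pacc_version = 0.10)

  # population covariate means implied by the mixture
  pop_mean <- function(m) sum(mixing * m)
  centers <- c(
    active_treatment = pop_mean(covariates$arm[, 3]),
    ptau217 = pop_mean(covariates$normal$ptau217$mean),
    amyloid_suvr = 1.01 + pop_mean(covariates$normal$amyloid_centiloid$mean) / 183,
    apoe4_carrier = pop_mean(covariates$bernoulli$apoe4_carrier),
    sex_female = pop_mean(covariates$bernoulli$sex_female),
    age = pop_mean(covariates$normal$age$mean),
    education = pop_mean(covariates$normal$education$mean),
    hipp_atrophy_z = pop_mean(covariates$normal$hipp_atrophy_z$mean),
    pacc_version = 0)

  identity_tf <- structure(list(lambda = 1, shift = 1),
                           class = "boxcox_transform")

  truth <- simulation_truth(
    n_subjects = n_subjects, mixing = mixing, alpha = alpha, basis = basis,
    zeta = matrix(0, 2, 1), gamma = gamma, covariate_centers = centers,
    covariates = covariates, sigma_b = 2.0, sigma_e = 1.25,
    boxcox = identity_tf,
    visit_schedule = c(seq(0, 3, by = 0.5), 4:7),
    dropout_hazard = c(0.045, 0.06, 0.08),
    cdr_progression_prob = c(0.228, 0.719, 0.882),
    biomarker_slopes = list(
      slope = list(amyloid_centiloid = c(1.5, 3.5, 5.0),
                   ptau217 = c(0.005, 0.02, 0.04),
                   hippocampal_volume = c(-30, -60, -90)),
      slope_sd = 0,
      noise_sd = list(amyloid_centiloid = 4, ptau217 = 0.02,
                      hippocampal_volume = 60),
      baseline = list(hippocampal_volume = 7500)),
    seed = 20260121L)

  truth$zeta <- derive_membership_zeta(truth, derive_n, derive_seed)
  truth
}

# Fit a multinomial logit of component label on raw covariates over a large
# internal draw; the result becomes the generative membership model, so the
# simulated membership mechanism is exactly multinomial-logit.
derive_membership_zeta <- function(truth, derive_n, derive_seed) {
  set.seed(derive_seed)
  comp <- sample.int(truth$G, derive_n, replace = TRUE, prob = truth$mixing)
  cov <- draw_covariates(truth, comp)
  memb <- c("active_treatment", "ptau217", "amyloid_suvr", "apoe4_carrier",
            "sex_female", "age", "education", "hipp_atrophy_z")
  df <- cov[, memb]
  df$.class <- factor(comp)
  fit <- nnet::multinom(.class ~ ., data = df, trace = FALSE, maxit = 400)
  zeta <- stats::coef(fit)
  if (is.null(dim(zeta))) zeta <- matrix(zeta, nrow = 1)
  colnames(zeta) <- c("(Intercept)", memb)
  zeta
}

#' Serialize / restore a simulation truth as JSON
#'
#' @param truth A \code{simulation_truth}.
#' @param path JSON path.
#' @export
truth_to_json <- function(truth, path) {
  rec <- unclass(truth)
  rec$basis <- unclass(rec$basis)
  rec$boxcox <- unclass(rec$boxcox)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
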