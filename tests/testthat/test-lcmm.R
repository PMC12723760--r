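# Shared small synthetic cohort fitted once and reused across blocks.
truth_s <- preset_a4learn_like(derive_n = 8000)
sim_s <- simulate_cohort(truth_s, n = 400, seed = 71)
fit_s <- suppressWarnings(
  fit_lcmm(sim_s$cohort, lcmm_spec(G = 3, spline_df = 2), n_starts = 2,
           seed = 17, transform = truth_s$boxcox))

test_that("log-likelihood matches a brute-force dense-matrix oracle", {
  set.seed(99)
  for (case in 1:12) {
    G <- sample(1:3, 1)
    n_sub <- sample(2:5, 1)
    n_vis <- sample(2:4, 1)
    ldata <- make_toy_ldata(n_sub, n_vis, seed = 100 + case,
                            with_covariates = case %% 2 == 0)
    q <- ncol(ldata$S)
    alpha <- matrix(rnorm(G * q), G, q)
    gamma <- rnorm(cogmix:::n_gamma(ldata))
    zeta <- if (G > 1) matrix(rnorm((G - 1) * ncol(ldata$X), 0, 0.5),
                              G - 1, ncol(ldata$X)) else NULL
    sb <- runif(1, 0.3, 2); se <- runif(1, 0.3, 2)
    got <- lcmm_loglik(ldata, alpha, gamma, sb, se, zeta = zeta)
    want <- oracle_loglik(ldata, alpha, gamma, sb, se, zeta = zeta)
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("a mixture of identical components collapses to the G=1 value", {
  ldata <- make_toy_ldata(5, 3, seed = 55)
  q <- ncol(ldata$S)
  a1 <- rnorm(q)
  ll1 <- lcmm_loglik(ldata, matrix(a1, 1), numeric(0), 1.2, 0.8)
  ll2 <- lcmm_loglik(ldata, rbind(a1, a1), numeric(0), 1.2, 0.8,
                     zeta = matrix(0, 1, ncol(ldata$X)))
  expect_equal(ll2, ll1, tolerance = 1e-10)
})

test_that("likelihood is invariant under consistent class relabelling", {
  ldata <- make_toy_ldata(5, 4, seed = 77, with_covariates = TRUE)
  q <- ncol(ldata$S)
  set.seed(7)
  alpha <- matrix(rnorm(3 * q), 3, q)
  gamma <- rnorm(cogmix:::n_gamma(ldata))
  zeta <- matrix(rnorm(2 * ncol(ldata$X), 0, 0.5), 2, ncol(ldata$X))
  base <- lcmm_loglik(ldata, alpha, gamma, 1, 1, zeta = zeta)
  for (perm in cogmix:::all_permutations(3)) {
    eta <- rbind(0, zeta)[perm, , drop = FALSE]
    zeta_p <- sweep(eta, 2, eta[1, ])[-1, , drop = FALSE]
    ll <- lcmm_loglik(ldata, alpha[perm, , drop = FALSE], gamma, 1, 1,
                      zeta = zeta_p)
    expect_equal(ll, base, tolerance = 1e-9)
  }
})

test_that("degenerate variance raises an error", {
  ldata <- make_toy_ldata(3, 3, seed = 5)
  expect_error(lcmm_loglik(ldata, matrix(0, 1, 2), numeric(0), 0, 0),
               "degenerate")
})

test_that("EM log-likelihood is monotone and the fit recovers the truth", {
  expect_monotone_trace(fit_s)
  expect_true(fit_s$converged)
  # class proportions near the generating mixture
  props <- colMeans(fit_s$posterior)
  emp <- as.vector(table(factor(sim_s$true_class, 1:3))) / 400
  expect_lt(max(abs(props - emp)), 0.06)
  # residual and random-intercept SDs near truth
  expect_lt(abs(fit_s$sigma_e - truth_s$sigma_e) / truth_s$sigma_e, 0.15)
  expect_lt(abs(fit_s$sigma_b - truth_s$sigma_b) / truth_s$sigma_b, 0.20)
  # canonical ordering: class 1 highest at maximum follow-up
  Send <- cbind(1, eval_spline_basis(fit_s$basis,
                                     fit_s$basis$boundary_knots[2]))
  ends <- as.vector(Send %*% t(fit_s$alpha))
  expect_true(all(diff(ends) < 0))
  # modal labels agree with the generating classes for most subjects
  agree <- mean(fit_s$class_labels[names(sim_s$true_class)] ==
                  sim_s$true_class)
  expect_gt(agree, 0.85)
})

test_that("G=1 EM solution matches an independent direct optimizer", {
  truth <- make_simple_truth(sigma_b = 1, sigma_e = 0.7, n = 40,
                             schedule = c(0, 1, 2, 3))
  sim <- simulate_cohort(truth, seed = 19)
  spec1 <- lcmm_spec(G = 1, spline_df = 1,
                     longitudinal_covariates = character(0),
                     membership_covariates = character(0),
                     standardize = FALSE)
  fit <- fit_lcmm(sim$cohort, spec1, n_starts = 1, seed = 1,
                  transform = truth$boxcox, tol = 1e-10, maxit = 2000)
  ldata <- fit$data
  q <- ncol(ldata$S)
  # direct route: profile out the GLS mean at each variance pair, optimize
  # the marginal likelihood over (log sb, log se) with the dense oracle
  profile_ll <- function(vp) {
    vm <- cogmix:::pattern_vmats(ldata$patterns, vp, "intercept")
    up <- cogmix:::gls_update(ldata, matrix(1, ldata$n_subjects, 1), vm)
    oracle_loglik(ldata, up$alpha, up$gamma, exp(vp[1]), exp(vp[2]))
  }
  opt <- optim(log(c(1, 0.7)), profile_ll, method = "Nelder-Mead",
               control = list(fnscale = -1, reltol = 1e-14, maxit = 2000))
  expect_equal(fit$loglik, opt$value, tolerance = 1e-6)
})

test_that("posterior probabilities are normalized and prior-dominated when
           components are identical", {
  tau <- posterior_probs(fit_s)
  expect_equal(unname(rowSums(tau)), rep(1, nrow(tau)), tolerance = 1e-10)

  fit_eq <- fit_s
  fit_eq$alpha <- fit_s$alpha[c(1, 1, 1), ]
  tau_eq <- posterior_probs(fit_eq)
  lp <- cogmix:::membership_logpi(fit_s$data$X, fit_s$zeta,
                                  fit_s$data$n_subjects)
  expect_equal(unname(tau_eq), exp(lp - cogmix:::logsumexp_rows(lp)),
               tolerance = 1e-9)
})

test_that("posteriors approach hard indicators for well-separated classes", {
  # two classes 10 sigma apart at every visit
  basis <- build_spline_basis(c(0, 4), 1)
  tf <- structure(list(lambda = 1, shift = 1), class = "boxcox_transform")
  truth <- simulation_truth(
    n_subjects = 120, mixing = c(0.5, 0.5),
    alpha = rbind(c(20, 0), c(0, 0)), basis = basis,
    zeta = matrix(0, 1, 2,
                  dimnames = list(NULL, c("(Intercept)", "sex_female"))),
    gamma = c(sex_female = 0),
    covariate_centers = c(sex_female = 0.5),
    covariates = list(normal = list(),
                      bernoulli = list(sex_female = c(0.5, 0.5))),
    sigma_b = 1, sigma_e = 1, boxcox = tf,
    visit_schedule = 0:4, dropout_hazard = 0, seed = 2)
  sim <- simulate_cohort(truth, seed = 23)
  spec <- lcmm_spec(G = 2, spline_df = 1,
                    longitudinal_covariates = "sex_female",
                    membership_covariates = "sex_female")
  fit <- fit_lcmm(sim$cohort, spec, n_starts = 1, seed = 3,
                  transform = tf)
  expect_monotone_trace(fit)
  expect_gt(min(apply(fit$posterior, 1, max)), 0.999)
})

test_that("information criteria definitions hold", {
  expect_equal(fit_s$BIC, -2 * fit_s$loglik +
                 fit_s$n_params * log(fit_s$data$n_subjects))
  expect_gte(fit_s$ICL, fit_s$BIC)
  ic <- information_criteria(fit_s)
  expect_equal(unname(ic["ICL"] - ic["BIC"]), 2 * fit_s$entropy)

  # hard posteriors give zero entropy, so ICL = BIC
  fit_hard <- fit_s
  hard <- diag(3)[max.col(fit_s$posterior), ]
  fit_hard$posterior <- hard
  tl <- hard * log(pmax(hard, 1e-300))
  expect_equal(-sum(tl), 0)
})

test_that("standardized and raw covariate fits are reparameterizations", {
  spec_raw <- lcmm_spec(G = 3, spline_df = 2, standardize = FALSE)
  ldata_raw <- prepare_lcmm_data(sim_s$cohort, spec_raw,
                                 transform = truth_s$boxcox,
                                 basis = fit_s$basis)
  # map the standardized fit's parameters to the raw scale
  sc <- fit_s$scaling
  gnames <- names(fit_s$gamma)
  centers <- vapply(gnames, function(nm)
    if (!is.null(sc[[nm]])) sc[[nm]]["center"] else 0, numeric(1))
  scales <- vapply(gnames, function(nm)
    if (!is.null(sc[[nm]])) sc[[nm]]["scale"] else 1, numeric(1))
  gamma_raw <- fit_s$gamma / scales
  alpha_raw <- fit_s$alpha
  alpha_raw[, 1] <- alpha_raw[, 1] - sum(fit_s$gamma * centers / scales)
  mnames <- colnames(fit_s$data$X)[-1]
  mc <- vapply(mnames, function(nm)
    if (!is.null(sc[[nm]])) sc[[nm]]["center"] else 0, numeric(1))
  ms <- vapply(mnames, function(nm)
    if (!is.null(sc[[nm]])) sc[[nm]]["scale"] else 1, numeric(1))
  zeta_raw <- fit_s$zeta
  zeta_raw[, -1] <- sweep(fit_s$zeta[, -1, drop = FALSE], 2, ms, "/")
  zeta_raw[, 1] <- fit_s$zeta[, 1] -
    as.vector(fit_s$zeta[, -1, drop = FALSE] %*% (mc / ms))
  ll_raw <- lcmm_loglik(ldata_raw, alpha_raw, gamma_raw, fit_s$sigma_b,
                        fit_s$sigma_e, zeta = zeta_raw)
  expect_equal(ll_raw, fit_s$loglik, tolerance = 1e-6)
})

test_that("empty-class collapse is flagged", {
  expect_true(length(fit_s$empty_classes) == 0)
  # a fit whose third class is given no mass
  fit_bad <- fit_s
  fit_bad$posterior[, 3] <- 0
  expect_lt(max(fit_bad$posterior[, 3]), 1e-6)
})
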