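test_that("stratified folds partition subjects with balanced sizes", {
  ids <- sprintf("S%03d", 1:100)
  labs <- setNames(rep("a", 100), ids)
  ptau <- setNames(rep(0.2, 100), ids)   # single stratum
  f <- make_folds(labs, ptau, K = 10, seed = 1)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) == 10))
  expect_setequal(names(f), ids)

  # mixed strata still partition, sizes within each stratum differ by <= 1
  labs2 <- setNames(sample(c("a", "b", "c"), 100, TRUE, c(.7, .2, .1)), ids)
  ptau2 <- setNames(runif(100), ids)
  f2 <- make_folds(labs2, ptau2, K = 10, seed = 2)
  expect_equal(sum(table(f2)), 100)
  strata <- attr(f2, "strata")
  for (s in unique(strata)) {
    sz <- table(factor(f2[names(strata)[strata == s]], 1:10))
    expect_lte(diff(range(sz)), 1)
  }

  # a stratum of size 7 spreads over 7 distinct folds
  labs3 <- setNames(rep("a", 7), sprintf("T%d", 1:7))
  f3 <- make_folds(labs3, setNames(rep(1, 7), names(labs3)), K = 10,
                   seed = 3)
  expect_equal(length(unique(f3)), 7)
  expect_error(make_folds(labs3, setNames(rep(1, 7), names(labs3)), K = 1),
               "K")
})

# A shared, strongly separated two-class cohort for prediction tests:
# classes differ by ~10 within-class SDs at every visit including baseline.
sep_truth <- local({
  basis <- build_spline_basis(c(0, 4), 1)
  tf <- structure(list(lambda = 1, shift = 1), class = "boxcox_transform")
  simulation_truth(
    n_subjects = 200, mixing = c(0.6, 0.4),
    alpha = rbind(c(15, -2), c(0, -2)), basis = basis,
    zeta = matrix(c(-0.4, 0), 1, 2,
                  dimnames = list(NULL, c("(Intercept)", "sex_female"))),
    gamma = c(sex_female = 0),
    covariate_centers = c(sex_female = 0.5),
    covariates = list(normal = list(),
                      bernoulli = list(sex_female = c(0.5, 0.5))),
    sigma_b = 1, sigma_e = 1, boxcox = tf,
    visit_schedule = 0:4, dropout_hazard = 0.03, seed = 5)
})
sep_spec <- lcmm_spec(G = 2, spline_df = 1,
                      longitudinal_covariates = "sex_female",
                      membership_covariates = "sex_female")
sep_sim <- simulate_cohort(sep_truth, seed = 61)
sep_fit <- fit_lcmm(sep_sim$cohort, sep_spec, n_starts = 1, seed = 6,
                    transform = sep_truth$boxcox)

test_that("baseline-only prediction matches the one-visit closed form", {
  p <- predict_class_baseline(sep_fit, sep_sim$cohort)
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-12)

  # hand computation for a few subjects: pi_g * N(z0; mu_g0, sb^2 + se^2)
  ld <- sep_fit$data
  for (id in rownames(p)[1:5]) {
    i <- match(id, ld$subject_id)
    rows <- which(ld$obs_subject == i)
    r0 <- rows[which.min(ld$times[rows])]
    eta <- c(0, sum(ld$X[i, ] * sep_fit$zeta))
    pri <- exp(eta) / sum(exp(eta))
    mu0 <- as.vector(cbind(1, eval_spline_basis(sep_fit$basis, 0)) %*%
                       t(sep_fit$alpha)) +
      sum(ld$Wb[i, ] * sep_fit$gamma)
    s2 <- sep_fit$sigma_b^2 + sep_fit$sigma_e^2
    num <- pri * dnorm(ld$z[r0], mu0, sqrt(s2))
    expect_equal(unname(p[id, ]), num / sum(num), tolerance = 1e-10)
  }
})

test_that("identical class trajectories reduce prediction to the prior", {
  fit_eq <- sep_fit
  fit_eq$alpha <- sep_fit$alpha[c(1, 1), ]
  p <- predict_class_baseline(fit_eq, sep_sim$cohort)
  ld <- fit_eq$data
  lp <- cogmix:::membership_logpi(ld$X, fit_eq$zeta, ld$n_subjects)
  pri <- exp(lp - cogmix:::logsumexp_rows(lp))
  expect_equal(unname(p[ld$subject_id, ]), unname(pri), tolerance = 1e-9)

  # prior-only mode ignores the outcome entirely
  p2 <- predict_class_baseline(sep_fit, sep_sim$cohort, use_outcome = FALSE)
  expect_equal(unname(p2[ld$subject_id, ]), unname(pri), tolerance = 1e-9)
  expect_true(all(rownames(p2) %in% attr(p2, "prior_only")))
})

test_that("cross-validation is leakage-free and covers each subject once", {
  labs <- sep_fit$class_labels
  ptau <- setNames(runif(length(labs)), names(labs))
  folds <- make_folds(labs, ptau, K = 5, seed = 7)
  cv <- cross_validate(sep_sim$cohort, sep_spec, folds, sep_fit,
                       n_starts = 1, seed = 8,
                       transform = sep_truth$boxcox)
  expect_setequal(cv$predictions$subject_id, names(labs))
  expect_equal(anyDuplicated(cv$predictions$subject_id), 0L)

  # permuting post-baseline outcomes of held-out subjects changes nothing
  fold1 <- names(folds)[folds == 1]
  co2 <- sep_sim$cohort
  later <- co2$visits$subject_id %in% fold1 & co2$visits$time_years > 0
  set.seed(99)
  co2$visits$pacc[later] <- sample(co2$visits$pacc[later])
  cv2 <- cross_validate(co2, sep_spec, folds, sep_fit, n_starts = 1,
                        seed = 8, transform = sep_truth$boxcox)
  p1 <- cv2$predictions[cv2$predictions$fold == 1, ]
  p0 <- cv$predictions[cv$predictions$fold == 1, ]
  expect_equal(p1[order(p1$subject_id), c("p_class1", "p_class2")],
               p0[order(p0$subject_id), c("p_class1", "p_class2")],
               tolerance = 1e-12, ignore_attr = TRUE)

  # near-oracle discrimination on 10-sigma-separated classes
  probs <- as.matrix(cv$predictions[, c("p_class1", "p_class2")])
  truthv <- labs[cv$predictions$subject_id]
  for (g in 1:2)
    expect_gt(pr_curve(probs[, g], as.integer(truthv == g))$auprc, 0.95)
})

test_that("average precision matches hand-enumerated values", {
  expect_equal(pr_curve(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))$auprc,
               (1 + 2 / 3) / 2)
  # 10-item toy, enumerated by hand: positives ranked 1, 3, 4, 8
  scores <- seq(1, 0.1, by = -0.1)
  pos <- c(1, 0, 1, 1, 0, 0, 0, 1, 0, 0)
  ap <- (1 * 1 + (2 / 3) * 1 + (3 / 4) * 1 + (4 / 8) * 1) / 4
  expect_equal(pr_curve(scores, pos)$auprc, ap)
  # perfect ranking and constant scores
  expect_equal(pr_curve(c(3, 2, 1), c(1, 1, 0))$auprc, 1)
  expect_equal(pr_curve(rep(1, 10), rep(c(1, 0), c(3, 7)))$auprc, 0.3)
  expect_error(pr_curve(1:3, c(0, 0, 0)), "no positive")
  # recall is non-decreasing down the threshold list
  set.seed(4)
  pc <- pr_curve(rnorm(50), rbinom(50, 1, 0.3))
  expect_true(all(diff(pc$recall) >= 0))
  expect_gte(pc$auprc, 0)
})

test_that("classification metrics match hand computations", {
  m0 <- classification_metrics(c(1, 2, 1), c(1, 2, 1))
  expect_equal(m0$accuracy, 1)
  expect_equal(m0$balanced_accuracy, 1)

  # confusion [[8,2],[1,9]]
  truthv <- rep(c(1, 2), each = 10)
  pred <- c(rep(1, 8), rep(2, 2), rep(2, 9), rep(1, 1))
  m <- classification_metrics(pred, truthv)
  expect_equal(m$accuracy, 17 / 20)
  expect_equal(m$balanced_accuracy, (0.8 + 0.9) / 2)
  expect_true(m$accuracy_ci["lower"] < 0.85 & m$accuracy_ci["upper"] > 0.85)

  # majority-vote predictor on a 77/16/7 split
  truth3 <- rep(1:3, c(77, 16, 7))
  m3 <- classification_metrics(rep(1, 100), truth3)
  expect_equal(m3$accuracy, 0.77)
  expect_equal(m3$balanced_accuracy, 1 / 3)

  # invariant to subject ordering
  set.seed(5)
  o <- sample(20)
  m_perm <- classification_metrics(pred[o], truthv[o])
  expect_equal(m_perm$accuracy, m$accuracy)
  expect_equal(m_perm$balanced_accuracy, m$balanced_accuracy)
})

test_that("any predictor beats the constant predictor's AUPRC floor", {
  set.seed(6)
  y <- rbinom(200, 1, 0.25)
  prev <- mean(y)
  informative <- y + rnorm(200, 0, 0.8)
  expect_gte(pr_curve(informative, y)$auprc, prev - 0.05)
})

test_that("classification agreement counts reclassified subjects", {
  a <- setNames(c(1, 1, 2, 3), sprintf("s%d", 1:4))
  expect_equal(classification_agreement(a, a),
               list(n_reclassified = 0L, fraction = 0, n_common = 4L),
               ignore_attr = TRUE)
  b <- setNames(c(rep(1, 9), 2), sprintf("t%d", 1:10))
  b2 <- b; b2["t1"] <- 2
  ag <- classification_agreement(b, b2)
  expect_equal(ag$n_reclassified, 1L)
  expect_equal(ag$fraction, 0.1)
  # consistent relabelling of both inputs leaves agreement unchanged
  relab <- c(2, 1)
  ag2 <- classification_agreement(setNames(relab[b], names(b)),
                                  setNames(relab[b2], names(b2)))
  expect_equal(ag2$n_reclassified, ag$n_reclassified)
  expect_error(classification_agreement(a, b), "overlap")
})
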