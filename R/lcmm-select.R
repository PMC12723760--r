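# Model-grid selection, class trajectory estimation, and the single-class
# random-slope variant used for longitudinal biomarkers.

#' Select spline degrees of freedom and number of classes
#'
#' Fits every combination of the degrees-of-freedom and class-number grids
#' and selects the minimum-BIC model (ICL reported alongside). Near-ties
#' (delta BIC < 2) are broken toward the model with fewer parameters, so the
#' selection is deterministic. Non-convergent cells are flagged and excluded
#' from the argmin with a warning.
#'
#' @param cohort A \code{cohort_data}.
#' @param df_grid,G_grid Integer grids (subsets of 1:3).
#' @param n_starts,seed Multi-start controls passed to [fit_lcmm()].
#' @param spec_base An \code{lcmm_spec} supplying covariates and random
#'   effects; its \code{G} and \code{spline_df} are overridden by the grids.
#' @param ... Passed to [fit_lcmm()].
#' @return List with \code{best_fit} (an \code{lcmm_fit}), \code{table}
#'   (data frame with G, df, loglik, n_params, BIC, ICL, delta_BIC,
#'   delta_ICL, converged, selected), and \code{fits} (all fitted cells).
#' @export
select_model <- function(cohort, df_grid = 1:3, G_grid = 1:3, n_starts = 5,
                         seed = 1, spec_base = lcmm_spec(), ...) {
  if (!length(df_grid) || !length(G_grid)) stopf("empty selection grid")
  fits <- list()
  rows <- list()
  cell <- 0L
  for (df in df_grid) for (G in G_grid) {
    cell <- cell + 1L
    spec <- spec_base
    spec$G <- as.integer(G); spec$spline_df <- as.integer(df)
    fit <- tryCatch(
      suppressWarnings(fit_lcmm(cohort, spec, n_starts = n_starts,
                                seed = derive_seed(seed, cell), ...)),
      error = function(e) NULL)
    key <- sprintf("G%d_df%d", G, df)
    fits[[key]] <- fit
    rows[[key]] <- data.frame(
      G = G, df = df,
      loglik = if (is.null(fit)) NA_real_ else fit$loglik,
      n_params = if (is.null(fit)) NA_integer_ else fit$n_params,
      BIC = if (is.null(fit)) NA_real_ else fit$BIC,
      ICL = if (is.null(fit)) NA_real_ else fit$ICL,
      converged = !is.null(fit) && fit$converged &&
        length(fit$empty_classes) == 0L)
  }
  tab <- do.call(rbind, rows)
  ok <- tab$converged & is.finite(tab$BIC)
  if (!any(ok)) stopf("no grid cell converged")
  if (any(!ok))
    warnf("%d grid cell(s) non-convergent or degenerate; excluded from selection",
          sum(!ok))
  cand <- which(ok & tab$BIC - min(tab$BIC[ok]) < 2)
  best_row <- cand[order(tab$n_params[cand], tab$BIC[cand])][1]
  tab$delta_BIC <- tab$BIC - tab$BIC[best_row]
  tab$delta_ICL <- tab$ICL - tab$ICL[best_row]
  tab$selected <- seq_len(nrow(tab)) == best_row
  rownames(tab) <- NULL
  list(best_fit = fits[[best_row]], table = tab, fits = fits)
}

# Pack/unpack (alpha, gamma) for the observed-information computation.
pack_mean_params <- function(alpha, gamma) c(t(alpha), gamma)
unpack_mean_params <- function(par, G, q, pl) {
  list(alpha = matrix(par[seq_len(G * q)], G, q, byrow = TRUE),
       gamma = if (pl) par[G * q + seq_len(pl)] else numeric(0))
}

# Central-difference Hessian of f at x.
num_hessian <- function(f, x, h = NULL) {
  p <- length(x)
  if (is.null(h)) h <- 1e-5 * pmax(abs(x), 1)
  H <- matrix(0, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- replace(numeric(p), i, h[i])
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    if (i < p) for (j in seq((i + 1), p)) {
      ej <- replace(numeric(p), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  H
}

# Observed-information covariance of (alpha, gamma), other parameters held
# at their estimates.
mean_param_cov <- function(fit) {
  ldata <- fit$data
  G <- fit$spec$G; q <- ncol(ldata$S); pl <- n_gamma(ldata)
  vm <- pattern_vmats(ldata$patterns, fit$vpar, fit$spec$random_effects)
  f <- function(par) {
    up <- unpack_mean_params(par, G, q, pl)
    ld <- class_logdens(ldata, up$alpha, up$gamma, vm)
    lp <- membership_logpi(ldata$X, fit$zeta, ldata$n_subjects)
    sum(logsumexp_rows(lp + ld))
  }
  H <- num_hessian(f, pack_mean_params(fit$alpha, fit$gamma))
  cov <- tryCatch(solve(-(H + t(H)) / 2), error = function(e) NULL)
  if (!is.null(cov) && any(diag(cov) < 0)) cov <- NULL
  cov
}

#' Estimated class mean trajectories with confidence bands
#'
#' Evaluates each class's model-implied mean outcome over a time grid at a
#' reference covariate profile (default: the covariate means of the fitting
#' data), with pointwise 95\% confidence intervals from the delta method on
#' the observed-information covariance of the trajectory coefficients and
#' shared effects. Means and interval endpoints are back-transformed through
#' the inverse Box-Cox to the observed outcome scale; since the inverse
#' transform is monotone increasing, interval endpoints map to interval
#' endpoints.
#'
#' @param fit An \code{lcmm_fit}.
#' @param times Numeric grid of years.
#' @param covariate_profile Optional named vector of covariate values on the
#'   raw scale; defaults to the design means.
#' @param level Confidence level.
#' @param ci Compute confidence bands (the observed-information Hessian is
#'   moderately expensive; set FALSE for point estimates only).
#' @return Data frame with columns \code{class, time, mean, ci_low, ci_high}
#'   on the observed outcome scale.
#' @export
class_trajectories <- function(fit, times = seq(0, fit$basis$boundary_knots[2],
                                                length.out = 25),
                               covariate_profile = NULL, level = 0.95,
                               ci = TRUE) {
  ldata <- fit$data
  G <- fit$spec$G; q <- ncol(ldata$S); pl <- n_gamma(ldata)
  Sg <- cbind(1, eval_spline_basis(fit$basis, times))

  wprof <- numeric(pl)
  if (pl) {
    means <- c(if (!is.null(ldata$Wb)) colMeans(ldata$Wb),
               if (!is.null(ldata$Wobs)) colMeans(ldata$Wobs))
    wprof <- means
    if (!is.null(covariate_profile)) {
      nm <- names(fit$gamma)
      for (j in seq_along(nm)) if (nm[j] %in% names(covariate_profile)) {
        sc <- fit$scaling[[nm[j]]] %||% c(center = 0, scale = 1)
        wprof[j] <- (covariate_profile[[nm[j]]] - sc["center"]) / sc["scale"]
      }
    }
  }
  offset <- if (pl) sum(wprof * fit$gamma) else 0

  cov <- NULL
  if (ci) {
    cov <- mean_param_cov(fit)
    if (is.null(cov))
      warnf("observed information is singular; confidence bands unavailable")
  }
  zq <- stats::qnorm(1 - (1 - level) / 2)
  out <- list()
  for (g in seq_len(G)) {
    m_t <- as.vector(Sg %*% fit$alpha[g, ]) + offset
    lo <- hi <- rep(NA_real_, length(times))
    if (!is.null(cov)) {
      J <- matrix(0, length(times), G * q + pl)
      J[, (g - 1) * q + seq_len(q)] <- Sg
      if (pl) J[, G * q + seq_len(pl)] <- matrix(wprof, length(times), pl,
                                                 byrow = TRUE)
      se <- sqrt(pmax(rowSums((J %*% cov) * J), 0))
      lo <- m_t - zq * se
      hi <- m_t + zq * se
    }
    out[[g]] <- data.frame(
      class = g, time = times,
      mean = inverse_boxcox(fit$transform, m_t),
      ci_low = if (all(is.na(lo))) lo else inverse_boxcox(fit$transform, lo),
      ci_high = if (all(is.na(hi))) hi else inverse_boxcox(fit$transform, hi))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Single-class linear mixed model for a longitudinal biomarker
#'
#' The G = 1 case of the latent class machinery with subject random
#' intercepts and slopes: natural cubic spline fixed effects for time
#' (default 2 degrees of freedom) on the biomarker's native scale (no
#' Box-Cox). Used to characterize longitudinal biomarker progression within
#' a class or group.
#'
#' @param series Data frame with columns \code{subject_id, time_years,
#'   value}; rows with missing values are dropped. At least 10 subjects need
#'   2+ visits.
#' @param spline_df Spline degrees of freedom (default 2).
#' @param maxit,tol Estimation controls.
#' @return An \code{lcmm_fit} with \code{spec$G = 1},
#'   \code{random_effects = "intercept+slope"}; its \code{D} is the 2x2
#'   random-effect covariance and \code{L} its lower Cholesky factor. Mean
#'   trajectories via [class_trajectories()] (identity transform).
#' @export
fit_biomarker_lmm <- function(series, spline_df = 2, maxit = 500, tol = 1e-6) {
  series <- series[stats::complete.cases(series[c("subject_id", "time_years",
                                                  "value")]), ]
  series <- series[order(series$subject_id, series$time_years), ]
  nv <- table(series$subject_id)
  if (sum(nv >= 2) < 10)
    stopf("fit_biomarker_lmm needs >= 2 visits for >= 10 subjects (got %d)",
          sum(nv >= 2))
  ids <- unique(series$subject_id)
  sid <- match(series$subject_id, ids)
  spec <- lcmm_spec(G = 1, spline_df = spline_df,
                    longitudinal_covariates = character(0),
                    membership_covariates = character(0),
                    random_effects = "intercept+slope", standardize = FALSE)
  identity_tf <- structure(list(lambda = 1, shift = 1),
                           class = "boxcox_transform")
  basis <- build_spline_basis(series$time_years, spline_df)
  pat <- build_patterns(length(ids), sid, series$time_years, NULL)
  ldata <- structure(list(
    z = series$value, S = cbind(1, eval_spline_basis(basis, series$time_years)),
    Wb = NULL, Wobs = NULL, X = matrix(1, length(ids), 1),
    obs_subject = sid, n_subjects = length(ids), n_obs = nrow(series),
    subject_id = as.character(ids), patterns = pat$patterns,
    fastpath = pat$fastpath, times = series$time_years,
    transform = identity_tf, basis = basis, scaling = list(), spec = spec
  ), class = "lcmm_data")
  fit_lcmm(ldata, spec, n_starts = 1, seed = 1, maxit = maxit, tol = tol)
}
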