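# EM estimation of the latent class mixed model.
#
# The observed-data likelihood for subject i with transformed outcomes y_i is
#   L_i = sum_g pi_ig * phi(y_i; S_i alpha_g + W_i gamma, V_i),
#   V_i = Z_i D Z_i' + sigma_e^2 I,  pi_ig = multinomial-logit(zeta' x_i).
# EM treats class membership as missing data; the M-step splits into a convex
# multinomial-logit subproblem (zeta), a tau-weighted GLS subproblem
# (alpha, gamma), and a low-dimensional variance maximization, each of which
# cannot decrease the expected complete-data log-likelihood, so the observed
# log-likelihood is non-decreasing across iterations.

# Variance parameter vector:
#   intercept:        (log sigma_b, log sigma_e)
#   intercept+slope:  (log L11, L21, log L22, log sigma_e), D = L L'
vpar_unpack <- function(vpar, re) {
  if (re == "intercept") {
    list(sb2 = exp(2 * vpar[1]), se2 = exp(2 * vpar[2]),
         sigma_b = exp(vpar[1]), sigma_e = exp(vpar[2]), D = NULL)
  } else {
    L <- matrix(c(exp(vpar[1]), vpar[2], 0, exp(vpar[3])), 2, 2)
    list(D = L %*% t(L), L = L, se2 = exp(2 * vpar[4]),
         sigma_b = sqrt((L %*% t(L))[1, 1]), sigma_e = exp(vpar[4]))
  }
}

# Per-pattern marginal covariance inverse and log-determinant.
pattern_vmats <- function(patterns, vpar, re) {
  vp <- vpar_unpack(vpar, re)
  lapply(patterns, function(p) {
    k <- p$k
    if (re == "intercept") {
      if (vp$se2 <= 0 && vp$sb2 <= 0)
        stopf("degenerate variance: sigma_b = sigma_e = 0")
      denom <- vp$se2 + k * vp$sb2
      Vinv <- diag(1 / vp$se2, k) - matrix(vp$sb2 / (vp$se2 * denom), k, k)
      list(Vinv = Vinv, logdet = (k - 1) * log(vp$se2) + log(denom))
    } else {
      Z <- cbind(1, p$times)
      V <- Z %*% vp$D %*% t(Z) + diag(vp$se2, k)
      ch <- chol(V)
      list(Vinv = chol2inv(ch), logdet = 2 * sum(log(diag(ch))))
    }
  })
}

# n_subjects x G matrix of log multivariate-normal densities per class.
class_logdens <- function(ldata, alpha, gamma, vm) {
  G <- nrow(alpha)
  mu <- ldata$S %*% t(alpha) + w_gamma(ldata, gamma)
  ld <- matrix(0, ldata$n_subjects, G)
  for (ip in seq_along(ldata$patterns)) {
    p <- ldata$patterns[[ip]]
    v <- vm[[ip]]
    m <- nrow(p$idx); k <- p$k
    Zp <- matrix(ldata$z[as.vector(p$idx)], m, k)
    for (g in seq_len(G)) {
      R <- Zp - matrix(mu[as.vector(p$idx) + (g - 1) * nrow(mu)], m, k)
      qf <- rowSums((R %*% v$Vinv) * R)
      ld[p$subjects, g] <- -0.5 * (k * log(2 * pi) + v$logdet + qf)
    }
  }
  ld
}

# n_subjects x G matrix of log prior class probabilities.
membership_logpi <- function(X, zeta, n) {
  if (is.null(zeta) || nrow(zeta) == 0L) return(matrix(0, n, 1L))
  eta <- cbind(0, X %*% t(zeta))
  eta - logsumexp_rows(eta)
}

#' Observed-data log-likelihood of a latent class mixed model
#'
#' Computes the mixture log-likelihood summed over subjects, each term a
#' log-sum-exp over classes of the log prior class probability plus the log
#' marginal Gaussian density of the subject's outcome vector (random effects
#' integrated out analytically).
#'
#' @param ldata An \code{lcmm_data} from [prepare_lcmm_data()].
#' @param alpha G x (1 + spline_df) matrix of class trajectory coefficients
#'   (intercept + spline columns).
#' @param gamma Shared covariate effects (may be length 0).
#' @param sigma_b,sigma_e Random-intercept and residual SDs (random-intercept
#'   structure), both > 0 jointly.
#' @param zeta Optional (G-1) x (1 + p) membership coefficient matrix
#'   (reference class 1); NULL means a single class.
#' @param D Optional 2x2 random intercept+slope covariance matrix; overrides
#'   \code{sigma_b}.
#' @return The scalar log-likelihood.
#' @export
lcmm_loglik <- function(ldata, alpha, gamma, sigma_b, sigma_e, zeta = NULL,
                        D = NULL) {
  alpha <- rbind(alpha)
  if (is.null(D)) {
    if (sigma_b <= 0 && sigma_e <= 0) stopf("degenerate variance: sigma_b = sigma_e = 0")
    vpar <- log(c(max(sigma_b, 1e-12), max(sigma_e, 1e-12)))
    re <- "intercept"
  } else {
    L <- t(chol(D))
    vpar <- c(log(L[1, 1]), L[2, 1], log(L[2, 2]), log(sigma_e))
    re <- "intercept+slope"
  }
  vm <- pattern_vmats(ldata$patterns, vpar, re)
  ld <- class_logdens(ldata, alpha, gamma, vm)
  lp <- membership_logpi(ldata$X, zeta, ldata$n_subjects)
  sum(logsumexp_rows(lp + ld))
}

# Joint tau-weighted GLS update of (alpha_1..alpha_G, gamma).
gls_update <- function(ldata, tau, vm) {
  G <- ncol(tau); q <- ncol(ldata$S)
  p_b <- if (is.null(ldata$Wb)) 0L else ncol(ldata$Wb)
  p_o <- if (is.null(ldata$Wobs)) 0L else ncol(ldata$Wobs)
  dim <- G * q + p_b + p_o
  A <- matrix(0, dim, dim); rhs <- numeric(dim)
  gi <- if (p_b) G * q + seq_len(p_b) else integer(0)
  oi <- if (p_o) G * q + p_b + seq_len(p_o) else integer(0)

  for (ip in seq_along(ldata$patterns)) {
    p <- ldata$patterns[[ip]]
    Vinv <- vm[[ip]]$Vinv
    m <- nrow(p$idx); k <- p$k
    S_p <- ldata$S[p$idx[1, ], , drop = FALSE]
    Zp <- matrix(ldata$z[as.vector(p$idx)], m, k)
    tau_p <- tau[p$subjects, , drop = FALSE]
    YV <- Zp %*% Vinv
    SY <- YV %*% S_p                      # row i = y_i' Vinv S
    SS <- crossprod(S_p, Vinv %*% S_p)
    if (p$fast) {
      vi1 <- rowSums(Vinv)                # Vinv 1_k
      u <- crossprod(S_p, vi1)            # S' Vinv 1
      c1 <- sum(vi1)
      y1 <- rowSums(YV)                   # 1' Vinv y_i
      Wb_p <- if (p_b) ldata$Wb[p$subjects, , drop = FALSE] else NULL
      if (p_o) {
        vobs <- p$vobs
        Sv <- crossprod(S_p, Vinv %*% vobs)
        cv <- crossprod(vobs, vi1)
        vv <- crossprod(vobs, Vinv %*% vobs)
        Yv <- YV %*% vobs
      }
      for (g in seq_len(G)) {
        w <- tau_p[, g]; sw <- sum(w)
        ai <- (g - 1) * q + seq_len(q)
        A[ai, ai] <- A[ai, ai] + sw * SS
        rhs[ai] <- rhs[ai] + crossprod(SY, w)
        if (p_b) {
          M <- u %*% t(crossprod(Wb_p, w))
          A[ai, gi] <- A[ai, gi] + M
          A[gi, ai] <- A[gi, ai] + t(M)
        }
        if (p_o) {
          A[ai, oi] <- A[ai, oi] + sw * Sv
          A[oi, ai] <- A[oi, ai] + sw * t(Sv)
        }
      }
      if (p_b) {
        A[gi, gi] <- A[gi, gi] + c1 * crossprod(Wb_p)
        rhs[gi] <- rhs[gi] + crossprod(Wb_p, y1)
      }
      if (p_o) {
        A[oi, oi] <- A[oi, oi] + m * vv
        rhs[oi] <- rhs[oi] + colSums(Yv)
        if (p_b) {
          M <- crossprod(Wb_p, rep(1, m)) %*% t(cv)
          A[gi, oi] <- A[gi, oi] + M
          A[oi, gi] <- A[oi, gi] + t(M)
        }
      }
    } else {
      # general path: per-subject observation-level covariates
      for (ii in seq_len(m)) {
        rows <- p$idx[ii, ]
        W_i <- cbind(
          if (p_b) matrix(ldata$Wb[p$subjects[ii], ], k, p_b, byrow = TRUE),
          if (p_o) ldata$Wobs[rows, , drop = FALSE])
        F_i <- cbind(S_p, W_i)
        C <- crossprod(F_i, Vinv %*% F_i)
        r <- crossprod(F_i, Vinv %*% ldata$z[rows])
        wi <- if (length(gi) + length(oi)) c(gi, oi) else integer(0)
        for (g in seq_len(G)) {
          tg <- tau_p[ii, g]
          ai <- (g - 1) * q + seq_len(q)
          A[ai, ai] <- A[ai, ai] + tg * C[seq_len(q), seq_len(q)]
          rhs[ai] <- rhs[ai] + tg * r[seq_len(q)]
          if (length(wi)) {
            A[ai, wi] <- A[ai, wi] + tg * C[seq_len(q), -seq_len(q), drop = FALSE]
            A[wi, ai] <- A[wi, ai] + tg * t(C[seq_len(q), -seq_len(q), drop = FALSE])
          }
        }
        if (length(wi)) {
          A[wi, wi] <- A[wi, wi] + C[-seq_len(q), -seq_len(q), drop = FALSE]
          rhs[wi] <- rhs[wi] + r[-seq_len(q)]
        }
      }
    }
  }
  beta <- solve(A, rhs)
  list(alpha = matrix(beta[seq_len(G * q)], G, q, byrow = TRUE),
       gamma = beta[seq(G * q + 1, length.out = p_b + p_o)],
       xtvx = A)
}

# Expected complete-data log-likelihood in the variance parameters, with
# class means and tau held fixed.
variance_q <- function(vpar, ldata, resid, tau, re) {
  vm <- tryCatch(pattern_vmats(ldata$patterns, vpar, re),
                 error = function(e) NULL)
  if (is.null(vm)) return(-Inf)
  q <- 0
  G <- ncol(tau)
  for (ip in seq_along(ldata$patterns)) {
    p <- ldata$patterns[[ip]]
    v <- vm[[ip]]
    k <- p$k
    tau_p <- tau[p$subjects, , drop = FALSE]
    for (g in seq_len(G)) {
      R <- resid[[ip]][[g]]
      qf <- rowSums((R %*% v$Vinv) * R)
      q <- q + sum(tau_p[, g] * (-0.5 * (k * log(2 * pi) + v$logdet + qf)))
    }
  }
  q
}

update_variance <- function(ldata, alpha, gamma, tau, vpar, re) {
  mu <- ldata$S %*% t(alpha) + w_gamma(ldata, gamma)
  G <- ncol(tau)
  resid <- lapply(ldata$patterns, function(p) {
    m <- nrow(p$idx)
    Zp <- matrix(ldata$z[as.vector(p$idx)], m, p$k)
    lapply(seq_len(G), function(g)
      Zp - matrix(mu[as.vector(p$idx) + (g - 1) * nrow(mu)], m, p$k))
  })
  if (re == "intercept") {
    # Closed-form EM update with the random intercept as additional missing
    # data: for fixed tau and means this is one EM iteration for the
    # marginal variances, so the expected log-likelihood cannot decrease.
    vp <- vpar_unpack(vpar, re)
    sb2 <- vp$sb2; se2 <- vp$se2
    num_b <- 0; num_e <- 0; n_obs <- 0
    for (ip in seq_along(ldata$patterns)) {
      p <- ldata$patterns[[ip]]
      k <- p$k
      d <- se2 + k * sb2
      vb <- sb2 * se2 / d                    # posterior variance of b
      tau_p <- tau[p$subjects, , drop = FALSE]
      for (g in seq_len(G)) {
        R <- resid[[ip]][[g]]
        sr <- rowSums(R)                     # sum of residuals
        eb <- sb2 * sr / d                   # posterior mean of b
        rss <- rowSums(R^2)
        w <- tau_p[, g]
        num_b <- num_b + sum(w * (eb^2 + vb))
        num_e <- num_e + sum(w * (rss - 2 * eb * sr + k * eb^2 + k * vb))
      }
      n_obs <- n_obs + nrow(R) * k
    }
    new <- 0.5 * log(c(max(num_b / ldata$n_subjects, 1e-12),
                       max(num_e / n_obs, 1e-12)))
    q0 <- variance_q(vpar, ldata, resid, tau, re)
    q1 <- variance_q(new, ldata, resid, tau, re)
    return(if (q1 >= q0 - 1e-10) new else vpar)
  }
  q0 <- variance_q(vpar, ldata, resid, tau, re)
  opt <- stats::optim(vpar, variance_q, ldata = ldata, resid = resid,
                      tau = tau, re = re, method = "Nelder-Mead",
                      control = list(fnscale = -1, maxit = 80, reltol = 1e-10))
  if (opt$value >= q0) opt$par else vpar
}

# Weighted multinomial-logit Newton-Raphson with fractional targets tau,
# warm-started from the current coefficients and safeguarded by step
# halving, so the expected log-likelihood in zeta never decreases.
update_zeta <- function(X, tau, zeta) {
  G <- ncol(tau)
  if (G < 2L) return(zeta)
  p <- ncol(X)
  qz <- function(z) sum(tau * membership_logpi(X, z, nrow(tau)))
  z <- zeta
  q_cur <- qz(z)
  for (it in seq_len(25)) {
    P <- exp(membership_logpi(X, z, nrow(tau)))
    grad <- as.vector(crossprod(X, tau[, -1, drop = FALSE] -
                                  P[, -1, drop = FALSE]))
    H <- matrix(0, p * (G - 1), p * (G - 1))
    for (g in 2:G) for (h in 2:G) {
      w <- if (g == h) P[, g] * (1 - P[, g]) else -P[, g] * P[, h]
      H[(g - 2) * p + seq_len(p), (h - 2) * p + seq_len(p)] <-
        crossprod(X, X * w)
    }
    step <- tryCatch(solve(H + diag(1e-8, nrow(H)), grad),
                     error = function(e) NULL)
    if (is.null(step)) break
    delta <- t(matrix(step, p, G - 1))
    lam <- 1
    repeat {
      z_new <- z + lam * delta
      q_new <- qz(z_new)
      if (q_new >= q_cur) break
      lam <- lam / 2
      if (lam < 1e-4) { z_new <- z; q_new <- q_cur; break }
    }
    improve <- q_new - q_cur
    z <- z_new; q_cur <- q_new
    if (improve < 1e-8) break
  }
  z
}

# Initial posteriors from k-means on (baseline outcome, crude slope).
init_tau <- function(ldata, G, seed, jitter = 0) {
  n <- ldata$n_subjects
  set.seed(seed)
  if (G == 1L) return(matrix(1, n, 1L))
  feats <- t(vapply(seq_len(n), function(i) {
    rows <- which(ldata$obs_subject == i)
    zi <- ldata$z[rows]; ti <- ldata$times[rows]
    slope <- if (length(rows) > 1 && diff(range(ti)) > 0)
      (zi[length(zi)] - zi[1]) / (ti[length(ti)] - ti[1]) else 0
    c(zi[1], slope)
  }, numeric(2)))
  feats <- scale(feats)
  feats[!is.finite(feats)] <- 0
  assign <- tryCatch(
    stats::kmeans(feats, centers = G, nstart = 5)$cluster,
    error = function(e) sample.int(G, n, replace = TRUE))
  tau <- matrix(0.1 / (G - 1), n, G)
  tau[cbind(seq_len(n), assign)] <- 0.9
  if (jitter > 0) {
    tau <- tau * matrix(stats::rexp(n * G)^jitter, n, G)
    tau <- tau / rowSums(tau)
  }
  tau
}

# One EM run from a given initial posterior.
em_run <- function(ldata, G, re, tau0, maxit, tol, param_tol = 1e-4) {
  q <- ncol(ldata$S)
  pm <- ncol(ldata$X)
  zeta <- if (G > 1L) matrix(0, G - 1L, pm) else matrix(0, 0L, pm)
  s0 <- stats::sd(ldata$z)
  vpar <- if (re == "intercept") log(c(s0 / sqrt(2), s0 / sqrt(2)))
          else c(log(s0 / sqrt(2)), 0, log(s0 / 10), log(s0 / sqrt(2)))

  tau <- tau0
  vm <- pattern_vmats(ldata$patterns, vpar, re)
  up <- gls_update(ldata, tau, vm)
  alpha <- up$alpha; gamma <- up$gamma
  if (G > 1L) zeta <- update_zeta(ldata$X, tau, zeta)
  # moment-based variance initialization from the initial assignment
  mu0 <- ldata$S %*% t(alpha) + w_gamma(ldata, gamma)
  g0 <- max.col(tau, ties.method = "first")
  r0 <- ldata$z - mu0[cbind(seq_len(ldata$n_obs), g0[ldata$obs_subject])]
  sm <- tapply(r0, ldata$obs_subject, mean)
  sb2 <- max(stats::var(as.vector(sm)), 1e-10)
  se2 <- max(stats::var(r0 - sm[ldata$obs_subject]), 1e-10, na.rm = TRUE)
  vpar <- if (re == "intercept") 0.5 * log(c(sb2, se2))
          else c(0.5 * log(sb2), 0, 0.5 * log(sb2 / 25), 0.5 * log(se2))
  vpar <- update_variance(ldata, alpha, gamma, tau, vpar, re)

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    vm <- pattern_vmats(ldata$patterns, vpar, re)
    ld <- class_logdens(ldata, alpha, gamma, vm)
    lp <- membership_logpi(ldata$X, zeta, ldata$n_subjects)
    m <- lp + ld
    lli <- logsumexp_rows(m)
    ll <- sum(lli)
    tau <- exp(m - lli)
    trace <- c(trace, ll)
    old <- c(alpha, gamma, zeta, vpar)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll

    if (G > 1L) zeta <- update_zeta(ldata$X, tau, zeta)
    up <- gls_update(ldata, tau, vm)
    alpha <- up$alpha; gamma <- up$gamma
    vpar <- update_variance(ldata, alpha, gamma, tau, vpar, re)
    if (max(abs(c(alpha, gamma, zeta, vpar) - old)) < param_tol &&
        it > 2) { converged <- TRUE
      vm <- pattern_vmats(ldata$patterns, vpar, re)
      ld <- class_logdens(ldata, alpha, gamma, vm)
      lp <- membership_logpi(ldata$X, zeta, ldata$n_subjects)
      m <- lp + ld; lli <- logsumexp_rows(m)
      ll <- sum(lli); tau <- exp(m - lli); trace <- c(trace, ll)
      break
    }
  }
  list(alpha = alpha, gamma = gamma, zeta = zeta, vpar = vpar, tau = tau,
       loglik = ll, trace = trace, converged = converged, n_iter = length(trace))
}

#' Fit a latent class mixed model by multi-start EM
#'
#' Runs EM from \code{n_starts} initializations (a k-means-based start plus
#' jittered perturbations), keeps the best achieved log-likelihood, and
#' canonicalizes class labels by the model-implied mean outcome at the
#' maximum follow-up time, descending — class 1 is the most "stable"
#' (highest) trajectory and class G the fastest decliner. The membership
#' submodel uses class 1 as its reference, so its coefficients read as
#' log-odds of the declining classes versus stable.
#'
#' @param cohort A \code{cohort_data}, or a prepared \code{lcmm_data}.
#' @param spec An \code{lcmm_spec} (ignored when \code{cohort} is already
#'   prepared).
#' @param n_starts Number of EM starts.
#' @param seed Integer seed controlling all starts.
#' @param transform,basis,scaling Optional preprocessing objects to reuse
#'   (see [prepare_lcmm_data()]).
#' @param maxit,tol EM iteration cap and absolute log-likelihood convergence
#'   tolerance.
#' @return An object of class \code{lcmm_fit}: membership coefficients
#'   \code{zeta}, class coefficients \code{alpha}, shared effects
#'   \code{gamma}, \code{sigma_b}, \code{sigma_e} (and \code{D} for
#'   intercept+slope), \code{loglik}, \code{n_params}, \code{BIC},
#'   \code{ICL}, posterior matrix \code{posterior}, \code{class_labels},
#'   convergence metadata, and the prepared \code{data}.
#' @export
fit_lcmm <- function(cohort, spec, n_starts = 10, seed = 1, transform = NULL,
                     basis = NULL, scaling = NULL, maxit = 500, tol = 1e-6) {
  ldata <- if (inherits(cohort, "lcmm_data")) cohort
           else prepare_lcmm_data(cohort, spec, transform, basis, scaling)
  spec <- ldata$spec
  G <- spec$G; re <- spec$random_effects

  best <- NULL
  n_used <- 0L
  for (s in seq_len(max(1L, n_starts))) {
    tau0 <- init_tau(ldata, G, derive_seed(seed, s), jitter = (s > 1) * 1)
    run <- tryCatch(em_run(ldata, G, re, tau0, maxit, tol),
                    error = function(e) NULL)
    n_used <- n_used + 1L
    if (!is.null(run) && (is.null(best) || run$loglik > best$loglik))
      best <- run
  }
  if (is.null(best)) stopf("no EM start converged to a valid solution")
  if (!best$converged)
    warnf("EM did not meet the convergence tolerance within %d iterations; best achieved state returned", maxit)

  fit <- finalize_fit(ldata, best, n_used, seed)
  fit
}

# Canonical class ordering, information criteria, labels.
finalize_fit <- function(ldata, run, n_starts_used, seed) {
  spec <- ldata$spec
  G <- spec$G
  vp <- vpar_unpack(run$vpar, spec$random_effects)
  q <- ncol(ldata$S)

  tmax <- ldata$basis$boundary_knots[2]
  Smax <- cbind(1, eval_spline_basis(ldata$basis, tmax))
  mu_end <- as.vector(Smax %*% t(run$alpha))
  ord <- order(mu_end, decreasing = TRUE)

  alpha <- run$alpha[ord, , drop = FALSE]
  tau <- run$tau[, ord, drop = FALSE]
  zeta <- run$zeta
  if (G > 1L) {
    eta <- rbind(0, run$zeta)          # rows = original classes
    eta <- eta[ord, , drop = FALSE]
    zeta <- sweep(eta, 2, eta[1, ])[-1, , drop = FALSE]
    colnames(zeta) <- colnames(ldata$X)
  }

  empty <- which(apply(tau, 2, max) < 1e-6)
  if (length(empty))
    warnf("class(es) %s collapsed to (near) zero posterior mass",
          paste(empty, collapse = ", "))

  n_params <- (G - 1) * ncol(ldata$X) + G * q + n_gamma(ldata) +
    if (spec$random_effects == "intercept") 2L else 4L
  N <- ldata$n_subjects
  bic <- -2 * run$loglik + n_params * log(N)
  tl <- tau * log(pmax(tau, 1e-300))
  tl[tau == 0] <- 0
  entropy <- -sum(tl)
  icl <- bic + 2 * entropy

  labels <- max.col(tau, ties.method = "first")
  names(labels) <- ldata$subject_id

  gamma <- run$gamma
  names(gamma) <- c(colnames(ldata$Wb), colnames(ldata$Wobs))

  structure(list(
    spec = spec, zeta = zeta, alpha = alpha, gamma = gamma,
    sigma_b = vp$sigma_b, sigma_e = vp$sigma_e, D = vp$D, L = vp$L,
    vpar = run$vpar,
    loglik = run$loglik, n_params = n_params, BIC = bic, ICL = icl,
    entropy = entropy, posterior = tau, class_labels = labels,
    converged = run$converged, n_iter = run$n_iter,
    n_starts_used = n_starts_used, seed = seed,
    loglik_trace = run$trace, empty_classes = empty,
    transform = ldata$transform, basis = ldata$basis,
    scaling = ldata$scaling, data = ldata
  ), class = "lcmm_fit")
}

#' @export
print.lcmm_fit <- function(x, ...) {
  cat(sprintf("<lcmm_fit> G = %d, spline df = %d, %s random effects\n",
              x$spec$G, x$spec$spline_df, x$spec$random_effects))
  cat(sprintf("  N = %d subjects, loglik = %.2f, BIC = %.2f, ICL = %.2f\n",
              x$data$n_subjects, x$loglik, x$BIC, x$ICL))
  cat(sprintf("  class proportions: %s\n",
              paste(sprintf("%.3f", colMeans(x$posterior)), collapse = " / ")))
  cat(sprintf("  sigma_b = %.3f, sigma_e = %.3f, converged = %s (%d iter)\n",
              x$sigma_b, x$sigma_e, x$converged, x$n_iter))
  invisible(x)
}

#' Posterior class probabilities
#'
#' Recomputes \code{tau_ig = pi_ig phi_ig / sum_h pi_ih phi_ih} from a fitted
#' model using each subject's full outcome vector. Subjects with no outcomes
#' in \code{newdata} receive their prior membership probabilities, with
#' attribute \code{prior_only} flagging them.
#'
#' @param fit An \code{lcmm_fit}.
#' @param newdata Optional \code{lcmm_data}; defaults to the fitting data.
#' @return N x G matrix of posterior probabilities (rows sum to 1).
#' @export
posterior_probs <- function(fit, newdata = NULL) {
  ldata <- newdata %||% fit$data
  vm <- pattern_vmats(ldata$patterns, fit$vpar, fit$spec$random_effects)
  ld <- class_logdens(ldata, fit$alpha, fit$gamma, vm)
  lp <- membership_logpi(ldata$X, fit$zeta, ldata$n_subjects)
  m <- lp + ld
  tau <- exp(m - logsumexp_rows(m))
  rownames(tau) <- ldata$subject_id
  tau
}

#' Information criteria of a fitted LCMM
#'
#' \code{BIC = -2 loglik + n_params log(N)} with N the number of subjects;
#' \code{ICL = BIC + 2 * posterior entropy}, the entropy-penalized variant
#' that rewards well-separated classes (so ICL >= BIC always).
#'
#' @param fit An \code{lcmm_fit}.
#' @return Named numeric vector \code{c(BIC, ICL)}.
#' @export
information_criteria <- function(fit) {
  c(BIC = fit$BIC, ICL = fit$ICL)
}
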