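# Class-specific clinical trial power under attrition. The "maximum possible
# benefit" construction anchors the treatment effect to the amyloid-negative
# stable group's mean trajectory: a hypothetical treatment can at best move a
# group's mean to that reference at the trial horizon.

#' Maximum possible treatment benefit at a horizon
#'
#' Difference between the reference (amyloid-negative stable) group mean and
#' the target group mean at the same horizon. A negative value (reference
#' below control) triggers a warning.
#'
#' @param mean_reference_max,mean_control Group means (outcome points).
#' @return The difference \code{reference - control}.
#' @export
max_benefit <- function(mean_reference_max, mean_control) {
  d <- mean_reference_max - mean_control
  if (any(d < 0)) warnf("maximum benefit is negative (reference below control)")
  d
}

#' Define a power scenario
#'
#' @param mean_control,sd_control Control-group mean and SD at the horizon.
#' @param mean_reference_max,sd_reference Reference-group (maximum-benefit
#'   anchor) mean and SD at the same horizon.
#' @param effect_fraction Fraction of the maximum benefit attributed to
#'   treatment, in (0, 1].
#' @param n_per_arm Randomized participants per arm.
#' @param attrition Fraction lost by the horizon, in [0, 1); analysis is on
#'   completers, \code{n_eff = round(n_per_arm * (1 - attrition))}.
#' @param alpha Two-sided significance level.
#' @param horizon_years Trial duration (annotation only).
#' @return An object of class \code{power_scenario}.
#' @export
power_scenario <- function(mean_control, sd_control, mean_reference_max,
                           sd_reference, effect_fraction = 1, n_per_arm = 500,
                           attrition = 0, alpha = 0.05, horizon_years = NA) {
  if (effect_fraction <= 0 || effect_fraction > 1)
    stopf("effect_fraction must be in (0, 1]")
  if (attrition < 0 || attrition >= 1) stopf("attrition must be in [0, 1)")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  if (sd_control <= 0 || sd_reference <= 0) stopf("SDs must be positive")
  n_eff <- round(n_per_arm * (1 - attrition))
  if (n_eff < 2) stopf("fewer than 2 completers per arm")
  structure(list(mean_control = mean_control, sd_control = sd_control,
                 mean_reference_max = mean_reference_max,
                 sd_reference = sd_reference,
                 effect_fraction = effect_fraction, n_per_arm = n_per_arm,
                 attrition = attrition, alpha = alpha,
                 horizon_years = horizon_years, n_eff = n_eff),
            class = "power_scenario")
}

#' Two-sample power for a class-specific trial
#'
#' Treatment effect \code{delta = effect_fraction * (mean_reference_max -
#' mean_control)}. The default is the normal approximation to the two-sample
#' t-test on completers,
#' \deqn{power = \Phi(d - z_{1-\alpha/2}) + \Phi(-d - z_{1-\alpha/2}),
#'   \quad d = |\delta| / (sd_p \sqrt{2/n_{eff}}),}
#' (both rejection tails, so the null case returns \code{alpha}), with
#' \code{sd_p} the equal-variance pooling of the two groups' SDs
#' (\code{sd_pooling = "control"} uses the control SD alone). The
#' \code{exact} mode computes noncentral-t power with
#' \code{2 n_eff - 2} degrees of freedom via [stats::power.t.test()].
#'
#' @param scenario A \code{power_scenario}.
#' @param method \code{"normal"} (default) or \code{"exact"}.
#' @param sd_pooling \code{"pooled"} (default) or \code{"control"}.
#' @return Power in (0, 1).
#' @export
power_two_sample <- function(scenario, method = c("normal", "exact"),
                             sd_pooling = c("pooled", "control")) {
  method <- match.arg(method)
  sd_pooling <- match.arg(sd_pooling)
  s <- scenario
  delta <- s$effect_fraction * (s$mean_reference_max - s$mean_control)
  sd_p <- switch(sd_pooling,
                 pooled = sqrt((s$sd_control^2 + s$sd_reference^2) / 2),
                 control = s$sd_control)
  if (method == "normal") {
    z_a <- stats::qnorm(1 - s$alpha / 2)
    d <- abs(delta) / (sd_p * sqrt(2 / s$n_eff))
    stats::pnorm(d - z_a) + stats::pnorm(-d - z_a)  # both rejection tails
  } else {
    if (abs(delta) < .Machine$double.eps) return(s$alpha)
    stats::power.t.test(n = s$n_eff, delta = abs(delta), sd = sd_p,
                        sig.level = s$alpha)$power
  }
}

#' Power table over groups, horizons and effect fractions
#'
#' @param groups Data frame with columns \code{group, horizon_years, mean,
#'   sd} (one row per group x horizon) including a row with
#'   \code{group == reference_group} at each horizon.
#' @param reference_group Name of the maximum-benefit anchor group.
#' @param fractions Effect fractions to tabulate.
#' @param n_per_arm,alpha Design constants.
#' @param attrition Named vector of attrition by horizon (names = horizon
#'   years as character), or a scalar.
#' @param ... Passed to [power_two_sample()].
#' @return Data frame: group, horizon_years, effect_fraction, delta,
#'   sd_pooled, n_eff, power.
#' @export
power_table <- function(groups, reference_group = "reference",
                        fractions = c(0.2, 1.0), n_per_arm = 500,
                        attrition = c("2" = 0.10, "4" = 0.20), alpha = 0.05,
                        ...) {
  rows <- list()
  for (h in unique(groups$horizon_years)) {
    gh <- groups[groups$horizon_years == h, , drop = FALSE]
    ref <- gh[gh$group == reference_group, , drop = FALSE]
    if (nrow(ref) != 1L) {
      warnf("no unique reference row at horizon %s; skipped", h)
      next
    }
    att <- if (length(attrition) == 1L && is.null(names(attrition)))
      attrition else unname(attrition[as.character(h)])
    if (is.na(att)) att <- 0
    for (i in seq_len(nrow(gh))) {
      if (gh$group[i] == reference_group) next
      for (f in fractions) {
        sc <- power_scenario(gh$mean[i], gh$sd[i], ref$mean, ref$sd,
                             effect_fraction = f, n_per_arm = n_per_arm,
                             attrition = att, alpha = alpha,
                             horizon_years = h)
        rows[[length(rows) + 1L]] <- data.frame(
          group = gh$group[i], horizon_years = h, effect_fraction = f,
          delta = f * (ref$mean - gh$mean[i]),
          sd_pooled = sqrt((gh$sd[i]^2 + ref$sd^2) / 2),
          n_eff = sc$n_eff, power = power_two_sample(sc, ...))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group means and SDs at trial horizons from a fitted LCMM
#'
#' For each class, the model-implied mean outcome at the horizon
#' (back-transformed) and the SD combining the uncertainty-free population
#' spread: \code{sqrt(sigma_b^2 + sigma_e^2)} on the transformed scale,
#' propagated to the observed scale by the delta method through the inverse
#' Box-Cox (derivative evaluated at the class mean).
#'
#' @param fit An \code{lcmm_fit}.
#' @param horizons Horizon times in years.
#' @return Data frame: group (class index), horizon_years, mean, sd.
#' @export
group_summaries_from_fit <- function(fit, horizons = c(2, 4)) {
  tr <- class_trajectories(fit, horizons, ci = FALSE)
  sd_t <- sqrt(fit$sigma_b^2 + fit$sigma_e^2)
  lam <- fit$transform$lambda
  # d/dz of inverse Box-Cox at the transformed-scale class mean
  Sg <- cbind(1, eval_spline_basis(fit$basis, tr$time))
  zmean <- vapply(seq_len(nrow(tr)), function(i)
    sum(Sg[i, ] * fit$alpha[tr$class[i], ]), numeric(1))
  deriv <- if (abs(lam) < 1e-12) exp(zmean) else (lam * zmean + 1)^(1 / lam - 1)
  data.frame(group = tr$class, horizon_years = tr$time,
             mean = tr$mean, sd = sd_t * abs(deriv))
}
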