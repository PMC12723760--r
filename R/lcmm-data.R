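# Model specification and design construction for the latent class mixed
# model. The prepared object groups subjects by visit-time pattern so the
# E-step and GLS updates can run on small dense matrices per pattern rather
# than per subject.

default_longitudinal_covariates <- c(
  "active_treatment", "ptau217", "amyloid_suvr", "apoe4_carrier",
  "sex_female", "age", "education", "hipp_atrophy_z", "pacc_version")

continuous_covariate_names <- c(
  "ptau217", "amyloid_suvr", "amyloid_centiloid", "age", "education",
  "hipp_atrophy_z", "tau_pet_composite")

#' Specify a latent class mixed model
#'
#' The longitudinal submodel has class-specific natural-spline time effects,
#' covariate effects shared across classes, and a subject random intercept
#' (optionally intercept + slope). The membership submodel is a multinomial
#' logit of baseline covariates; by convention it uses the longitudinal
#' covariates minus the test stimulus version, which is a visit-level
#' administration artifact rather than a subject characteristic.
#'
#' @param G Number of latent classes (>= 1).
#' @param spline_df Natural cubic spline degrees of freedom (1, 2 or 3).
#' @param longitudinal_covariates Covariates with effects shared across
#'   classes in the longitudinal submodel. Subject-level names are looked up
#'   in the baseline table; \code{pacc_version} is taken per visit.
#' @param membership_covariates Baseline covariates of the multinomial-logit
#'   membership submodel.
#' @param random_effects \code{"intercept"} or \code{"intercept+slope"}.
#' @param standardize Standardize continuous covariates to mean 0, SD 1
#'   (coefficients and odds ratios are then per-SD); binary covariates stay
#'   0/1. The scaling is stored and reused verbatim on held-out data.
#' @return An object of class \code{lcmm_spec}.
#' @export
lcmm_spec <- function(G = 3, spline_df = 2,
                      longitudinal_covariates = default_longitudinal_covariates,
                      membership_covariates =
                        setdiff(longitudinal_covariates, "pacc_version"),
                      random_effects = c("intercept", "intercept+slope"),
                      standardize = TRUE) {
  random_effects <- match.arg(random_effects)
  if (G < 1) stopf("G must be >= 1")
  if (!spline_df %in% 1:3) stopf("spline_df must be 1, 2 or 3")
  structure(list(G = as.integer(G), spline_df = as.integer(spline_df),
                 longitudinal_covariates = longitudinal_covariates,
                 membership_covariates = membership_covariates,
                 random_effects = random_effects,
                 standardize = isTRUE(standardize)),
            class = "lcmm_spec")
}

# Split covariate names into subject-level (baseline table) and
# observation-level (visits table) sources.
split_covariates <- function(covs, baseline, visits) {
  subj <- covs[covs %in% names(baseline)]
  obs <- setdiff(covs, subj)
  unknown <- obs[!obs %in% names(visits)]
  if (length(unknown))
    stopf("covariate(s) not found in baseline or visits: %s",
          paste(unknown, collapse = ", "))
  list(subject = subj, obs = obs)
}

#' Prepare cohort data for LCMM estimation
#'
#' Applies (or fits) the Box-Cox outcome transform, builds the natural spline
#' time basis and covariate designs, restricts to complete cases on the model
#' covariates, and groups subjects by visit-time pattern. When
#' \code{transform}, \code{basis} or \code{scaling} are supplied (e.g. from a
#' training fold) they are reused verbatim — nothing is re-estimated — which
#' is what makes held-out prediction leakage-free.
#'
#' @param cohort A \code{cohort_data}.
#' @param spec An \code{lcmm_spec}.
#' @param transform Optional \code{boxcox_transform} to reuse; default fits
#'   one on the pooled observed outcomes.
#' @param basis Optional \code{spline_basis} to reuse; default builds one on
#'   the pooled observation times.
#' @param scaling Optional covariate scaling list to reuse.
#' @return An object of class \code{lcmm_data}.
#' @export
prepare_lcmm_data <- function(cohort, spec, transform = NULL, basis = NULL,
                              scaling = NULL) {
  stopifnot(inherits(cohort, "cohort_data"), inherits(spec, "lcmm_spec"))
  b <- cohort$baseline
  v <- cohort$visits

  needs_z <- "hipp_atrophy_z" %in%
    union(spec$longitudinal_covariates, spec$membership_covariates)
  if (needs_z && !"hipp_atrophy_z" %in% names(b)) {
    ok <- stats::complete.cases(b[c("hippocampal_volume", "icv")])
    b$hipp_atrophy_z <- NA_real_
    if (sum(ok) >= 3)
      b$hipp_atrophy_z[ok] <- residualize_and_z(b$hippocampal_volume[ok], b$icv[ok])
  }

  cs <- split_covariates(spec$longitudinal_covariates, b, v)
  subj_covs <- union(cs$subject, spec$membership_covariates)
  if (length(miss <- setdiff(spec$membership_covariates, names(b))))
    stopf("membership covariate(s) missing from baseline: %s",
          paste(miss, collapse = ", "))

  keep_subj <- stats::complete.cases(b[, subj_covs, drop = FALSE])
  b <- b[keep_subj, , drop = FALSE]
  v <- v[v$subject_id %in% b$subject_id & !is.na(v$pacc), , drop = FALSE]
  if (length(cs$obs))
    v <- v[stats::complete.cases(v[, cs$obs, drop = FALSE]), , drop = FALSE]
  has_visit <- b$subject_id %in% v$subject_id
  b <- b[has_visit, , drop = FALSE]
  if (nrow(b) == 0L) stopf("no subjects remain after complete-case filtering")

  if (is.null(transform)) transform <- fit_boxcox(v$pacc)
  z <- apply_boxcox(transform, v$pacc)
  if (is.null(basis)) basis <- build_spline_basis(v$time_years, spec$spline_df)
  S <- cbind(1, eval_spline_basis(basis, v$time_years))

  if (is.null(scaling)) {
    scaling <- list()
    for (cv in intersect(union(subj_covs, cs$obs), continuous_covariate_names)) {
      x <- if (cv %in% names(b)) b[[cv]] else v[[cv]]
      scaling[[cv]] <- if (spec$standardize)
        c(center = mean(x), scale = stats::sd(x)) else c(center = 0, scale = 1)
    }
  }
  scale_col <- function(x, name) {
    sc <- scaling[[name]]
    if (is.null(sc) || sc["scale"] == 0) x else (x - sc["center"]) / sc["scale"]
  }

  Wb <- NULL
  if (length(cs$subject)) {
    Wb <- matrix(0, nrow(b), length(cs$subject),
                 dimnames = list(NULL, cs$subject))
    for (cv in cs$subject) Wb[, cv] <- scale_col(b[[cv]], cv)
  }
  Wobs <- NULL
  if (length(cs$obs)) {
    Wobs <- matrix(0, nrow(v), length(cs$obs),
                   dimnames = list(NULL, cs$obs))
    for (cv in cs$obs) Wobs[, cv] <- scale_col(v[[cv]], cv)
  }
  X <- matrix(1, nrow(b), 1L + length(spec$membership_covariates),
              dimnames = list(NULL, c("(Intercept)",
                                      spec$membership_covariates)))
  for (cv in spec$membership_covariates)
    X[, cv] <- scale_col(b[[cv]], cv)

  sid <- match(v$subject_id, b$subject_id)
  pat <- build_patterns(nrow(b), sid, v$time_years, Wobs)

  structure(list(
    z = z, S = S, Wb = Wb, Wobs = Wobs, X = X,
    obs_subject = sid, n_subjects = nrow(b), n_obs = nrow(v),
    subject_id = b$subject_id, patterns = pat$patterns,
    fastpath = pat$fastpath,
    times = v$time_years, transform = transform, basis = basis,
    scaling = scaling, spec = spec, baseline = b, visits = v
  ), class = "lcmm_data")
}

# Group subjects by visit-time pattern. obs rows must be sorted by subject
# then time. Each pattern stores the m x k matrix of observation-row indices,
# plus the pattern's observation-level covariate block when it is shared by
# all subjects in the pattern (the fast GLS path).
build_patterns <- function(n_subjects, obs_subject, times, Wobs) {
  subj_rows <- split(seq_along(obs_subject), obs_subject)
  key <- vapply(subj_rows, function(r) paste(round(times[r], 8), collapse = ","),
                character(1))
  patterns <- lapply(split(seq_len(n_subjects), key), function(subjects) {
    rows <- subj_rows[subjects]
    k <- length(rows[[1]])
    idx <- matrix(unlist(rows), ncol = k, byrow = TRUE)
    vobs <- NULL
    fast <- TRUE
    if (!is.null(Wobs)) {
      vobs <- Wobs[idx[1, ], , drop = FALSE]
      for (j in seq_len(ncol(Wobs))) {
        col <- matrix(Wobs[as.vector(idx), j], nrow = nrow(idx))
        if (max(abs(sweep(col, 2, vobs[, j]))) > 1e-12) { fast <- FALSE; break }
      }
    }
    list(subjects = subjects, idx = idx, k = k, times = times[idx[1, ]],
         vobs = vobs, fast = fast)
  })
  list(patterns = patterns,
       fastpath = all(vapply(patterns, function(p) p$fast, logical(1))))
}

# Per-observation shared-covariate contribution W %*% gamma.
w_gamma <- function(ldata, gamma) {
  out <- numeric(ldata$n_obs)
  p_b <- if (is.null(ldata$Wb)) 0L else ncol(ldata$Wb)
  if (p_b)
    out <- out + as.vector(ldata$Wb %*% gamma[seq_len(p_b)])[ldata$obs_subject]
  if (!is.null(ldata$Wobs))
    out <- out + as.vector(ldata$Wobs %*% gamma[p_b + seq_len(ncol(ldata$Wobs))])
  out
}

n_gamma <- function(ldata) {
  (if (is.null(ldata$Wb)) 0L else ncol(ldata$Wb)) +
    (if (is.null(ldata$Wobs)) 0L else ncol(ldata$Wobs))
}
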