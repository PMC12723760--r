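#' Fit a Box-Cox transformation by profile maximum likelihood
#'
#' Selects the Box-Cox power \code{lambda} that maximizes the normal profile
#' log-likelihood of the transformed values (including the Jacobian term
#' \code{(lambda - 1) * sum(log(y + shift))}). Because the cognitive composite
#' can be negative, a shift of \code{1 - min(y)} is applied first whenever
#' \code{min(y) <= 0}; the shift is stored with the fitted object so the
#' transform can be reused exactly on held-out data.
#'
#' @param y Numeric vector of outcome values (NAs dropped); at least 10 finite
#'   values are required.
#' @param lambda_range Search interval for \code{lambda}.
#' @param tol Golden-section convergence tolerance on \code{lambda}.
#' @return An object of class \code{boxcox_transform} with elements
#'   \code{lambda} and \code{shift}.
#' @examples
#' bc <- fit_boxcox(rlnorm(200))
#' z  <- apply_boxcox(bc, rlnorm(10))
#' @export
fit_boxcox <- function(y, lambda_range = c(-3, 3), tol = 1e-5) {
  y <- y[is.finite(y)]
  if (length(y) < 10L) stopf("fit_boxcox needs >= 10 finite values, got %d", length(y))
  if (stats::sd(y) == 0) stopf("fit_boxcox: input is constant, transform is degenerate")
  shift <- if (min(y) <= 0) 1 - min(y) else 0
  obj <- function(lambda) boxcox_profile_loglik(y, lambda, shift)

  # golden-section maximization on [a, b]
  gr <- (sqrt(5) - 1) / 2
  a <- lambda_range[1]; b <- lambda_range[2]
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- obj(x1); f2 <- obj(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- obj(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- obj(x1)
    }
  }
  structure(list(lambda = (a + b) / 2, shift = shift), class = "boxcox_transform")
}

# Profile log-likelihood of the Box-Cox model at a fixed lambda.
boxcox_profile_loglik <- function(y, lambda, shift) {
  ys <- y + shift
  z <- if (abs(lambda) < 1e-12) log(ys) else (ys^lambda - 1) / lambda
  n <- length(z)
  s2 <- sum((z - mean(z))^2) / n
  -n / 2 * log(s2) + (lambda - 1) * sum(log(ys))
}

#' Apply or invert a fitted Box-Cox transformation
#'
#' Forward: \code{((y + shift)^lambda - 1) / lambda} (natural log when
#' \code{lambda = 0}). Inverse is the exact algebraic inverse minus the shift.
#'
#' @param transform A \code{boxcox_transform}.
#' @param y,z Numeric vectors on the observed / transformed scale.
#' @return Numeric vector; NAs propagate.
#' @export
apply_boxcox <- function(transform, y) {
  ys <- y + transform$shift
  if (abs(transform$lambda - 1) < 1e-12) return(ys - 1)  # affine case
  bad <- which(is.finite(ys) & ys <= 0)
  if (length(bad))
    stopf("apply_boxcox: %d value(s) violate y + shift > 0 (first offender %.4g)",
          length(bad), y[bad[1]])
  if (abs(transform$lambda) < 1e-12) log(ys)
  else (ys^transform$lambda - 1) / transform$lambda
}

#' @rdname apply_boxcox
#' @export
inverse_boxcox <- function(transform, z) {
  lam <- transform$lambda
  if (abs(lam) < 1e-12) return(exp(z) - transform$shift)
  if (abs(lam - 1) < 1e-12) return(z + 1 - transform$shift)
  arg <- lam * z + 1
  bad <- which(is.finite(arg) & arg <= 0)
  if (length(bad))
    stopf("inverse_boxcox: %d value(s) violate lambda*z + 1 > 0 (first offender %.4g)",
          length(bad), z[bad[1]])
  arg^(1 / lam) - transform$shift
}

#' Natural cubic spline basis for follow-up time
#'
#' Builds a natural cubic spline basis with boundary knots at the minimum and
#' maximum observation time. Interior knots follow the degrees of freedom:
#' none for \code{df = 1}, the median observation time for \code{df = 2}, and
#' tertiles for \code{df = 3}. Knots are computed over all observation times
#' pooled across subjects and stored, so the basis can be evaluated
#' identically at new times (with linear extrapolation beyond the boundaries,
#' the natural-spline constraint).
#'
#' @param times Numeric vector of observation times (years); must span > 0.
#' @param df Degrees of freedom, one of 1, 2, 3.
#' @return An object of class \code{spline_basis} storing \code{df},
#'   \code{boundary_knots}, \code{interior_knots}.
#' @seealso [eval_spline_basis()]
#' @export
build_spline_basis <- function(times, df) {
  if (!df %in% 1:3) stopf("spline df must be 1, 2 or 3, got %s", df)
  times <- times[is.finite(times)]
  bk <- range(times)
  if (diff(bk) <= 0) stopf("build_spline_basis: times have zero span")
  interior <- switch(df,
    numeric(0),
    stats::median(times),
    unname(stats::quantile(times, c(1, 2) / 3))
  )
  structure(list(df = as.integer(df), boundary_knots = bk,
                 interior_knots = interior),
            class = "spline_basis")
}

#' Evaluate a stored natural cubic spline basis at new times
#'
#' @param basis A \code{spline_basis}.
#' @param times Numeric vector.
#' @return Matrix with \code{length(times)} rows and \code{basis$df} columns.
#' @export
eval_spline_basis <- function(basis, times) {
  m <- splines::ns(times,
                   knots = if (length(basis$interior_knots)) basis$interior_knots else NULL,
                   Boundary.knots = basis$boundary_knots)
  matrix(as.vector(m), nrow = length(times), ncol = basis$df,
         dimnames = list(NULL, paste0("ns", seq_len(basis$df))))
}

#' Hippocampal atrophy z-score: residualize volume on ICV, standardize, flip
#'
#' Ordinary least squares of volume on intracranial volume (with intercept);
#' residuals are z-scored and the sign flipped so that larger values mean more
#' atrophy (smaller residual volume).
#'
#' @param volume,icv Numeric vectors of equal length (n >= 3), mm^3.
#' @return Numeric vector with mean 0, SD 1, oriented so higher = more atrophy.
#' @export
residualize_and_z <- function(volume, icv) {
  if (length(volume) != length(icv)) stopf("volume and icv lengths differ")
  if (length(volume) < 3L) stopf("residualize_and_z needs n >= 3")
  if (stats::sd(icv) == 0) stopf("residualize_and_z: icv has zero variance (collinear with intercept)")
  r <- stats::lm.fit(cbind(1, icv), volume)$residuals
  s <- stats::sd(r)
  if (s < .Machine$double.eps^0.5 * max(1, stats::sd(volume)))
    stopf("residualize_and_z: residuals are degenerate (volume is an exact linear function of icv)")
  -(r - mean(r)) / s
}

#' Eight-region cortical tau PET composite
#'
#' Arithmetic mean SUVr over the eight cortical regions used for the tau
#' composite: entorhinal, inferior temporal, inferior parietal, posterior
#' cingulate, caudal middle frontal, middle temporal, superior parietal,
#' frontal pole.
#'
#' @param regional_suvr Named numeric vector or list containing all eight
#'   regions (names as in [tau_composite_regions]).
#' @return Mean SUVr, or \code{NA_real_} (with attribute \code{missing}) when
#'   any region is absent or NA — such subjects are excluded from tau models.
#' @export
tau_composite <- function(regional_suvr) {
  v <- unlist(regional_suvr)
  present <- tau_composite_regions %in% names(v)
  if (!all(present) || anyNA(v[tau_composite_regions])) {
    out <- NA_real_
    attr(out, "missing") <- tau_composite_regions[!present]
    return(out)
  }
  mean(v[tau_composite_regions])
}

#' @rdname tau_composite
#' @format NULL
#' @export
tau_composite_regions <- c(
  "entorhinal", "inferior_temporal", "inferior_parietal",
  "posterior_cingulate", "caudal_middle_frontal", "middle_temporal",
  "superior_parietal", "frontal_pole"
)

#' Serialize / restore fitted transforms
#'
#' Transforms are deterministic once fitted; JSON round-tripping them is what
#' guarantees that cross-validation folds and held-out prediction reuse
#' exactly the transform fitted on training data.
#'
#' @param x A \code{boxcox_transform} or \code{spline_basis}.
#' @param path File path for the JSON.
#' @return \code{transform_from_json} returns the restored object.
#' @export
transform_to_json <- function(x, path) {
  rec <- c(list(type = class(x)[1]), unclass(x))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname transform_to_json
#' @export
transform_from_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  type <- rec$type
  rec$type <- NULL
  if (identical(type, "spline_basis")) rec$interior_knots <- as.numeric(rec$interior_knots)
  structure(rec, class = type)
}
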