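# Prospective-discrimination machinery: stratified ten-fold cross-validation
# with per-fold refitting, baseline-only class prediction, precision-recall
# summaries, and cross-model classification agreement.

#' Stratified fold assignment
#'
#' Strata are the cross of class label and P-tau217 tertile (tertiles over
#' all subjects — a stratification variable, not a fitted quantity). Within
#' each stratum, subjects are shuffled (seeded) and dealt round-robin over a
#' shuffled fold order, so fold sizes within a stratum differ by at most one
#' and a stratum of size m < K spreads over m distinct folds.
#'
#' @param labels Named class vector (names = subject ids).
#' @param ptau Named numeric vector of baseline P-tau217, same subjects.
#' @param K Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Named integer vector of fold indices in 1..K, with attribute
#'   \code{strata}.
#' @export
make_folds <- function(labels, ptau, K = 10, seed = 1) {
  if (K < 2) stopf("K must be >= 2")
  ids <- names(labels)
  if (is.null(ids)) stopf("labels must be named by subject id")
  ptau <- ptau[ids]
  ter <- if (all(is.finite(ptau)) && length(unique(ptau)) > 3) {
    q <- stats::quantile(ptau, c(1, 2) / 3)
    1L + (ptau > q[1]) + (ptau > q[2])
  } else rep(1L, length(ids))
  strata <- paste(labels, ter, sep = ":")
  folds <- stats::setNames(integer(length(ids)), ids)
  set.seed(seed)
  for (s in unique(strata)) {
    members <- sample(ids[strata == s])
    fold_order <- sample.int(K)
    folds[members] <- fold_order[(seq_along(members) - 1L) %% K + 1L]
  }
  attr(folds, "strata") <- stats::setNames(strata, ids)
  folds
}

#' Baseline-only class prediction for new subjects
#'
#' Combines the fitted membership prior \code{pi_g(x)} with the Gaussian
#' density of the subject's single baseline outcome under each class (one
#' visit at t = 0, marginal variance \code{sigma_b^2 + sigma_e^2}), and
#' normalizes. The training fold's Box-Cox transform, spline knots and
#' covariate scaling are reused verbatim. With \code{use_outcome = FALSE}
#' (or for subjects without a baseline outcome) the membership prior alone
#' is returned; such rows are flagged in attribute \code{prior_only}.
#'
#' @param fit An \code{lcmm_fit}.
#' @param cohort A \code{cohort_data} containing the subjects to predict.
#' @param subjects Subject ids (default: all in \code{cohort}).
#' @param use_outcome Include the baseline outcome density (default) or use
#'   the membership prior alone.
#' @return Matrix (subjects x G) of class probabilities, rows summing to 1.
#' @export
predict_class_baseline <- function(fit, cohort, subjects = NULL,
                                   use_outcome = TRUE) {
  stopifnot(inherits(cohort, "cohort_data"))
  subjects <- subjects %||% cohort$baseline$subject_id
  v <- cohort$visits
  base_v <- v[v$subject_id %in% subjects & v$time_years == 0, , drop = FALSE]
  sub <- cohort_data(base_v, cohort$baseline[
    cohort$baseline$subject_id %in% subjects, , drop = FALSE])
  if (!use_outcome) sub$visits$pacc <- NA_real_

  ld <- tryCatch(
    prepare_lcmm_data(sub, fit$spec, transform = fit$transform,
                      basis = fit$basis, scaling = fit$scaling),
    error = function(e) NULL)
  G <- fit$spec$G
  out <- matrix(NA_real_, length(subjects), G,
                dimnames = list(subjects, NULL))
  if (!is.null(ld) && use_outcome) {
    tau <- posterior_probs(fit, ld)
    out[rownames(tau), ] <- tau
  }
  prior_only <- rownames(out)[!stats::complete.cases(out)]
  if (length(prior_only)) {
    b <- sub$baseline[match(prior_only, sub$baseline$subject_id), , drop = FALSE]
    bsub <- cohort_data(
      data.frame(subject_id = b$subject_id, time_years = 0, pacc = 0,
                 pacc_version = 1L, cdr_global = NA_real_,
                 cdr_memory = NA_real_),
      b)
    ldp <- prepare_lcmm_data(bsub, fit$spec, transform = fit$transform,
                             basis = fit$basis, scaling = fit$scaling)
    lp <- membership_logpi(ldp$X, fit$zeta, ldp$n_subjects)
    pri <- exp(lp - logsumexp_rows(lp))
    out[ldp$subject_id, ] <- pri
  }
  attr(out, "prior_only") <- prior_only
  out
}

all_permutations <- function(G) {
  if (G == 1) return(list(1L))
  out <- list()
  for (p in asplit(gtools_permutations(G), 1)) out[[length(out) + 1]] <- p
  out
}

# Small permutation enumerator (G <= 4 in practice).
gtools_permutations <- function(G) {
  if (G == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(G - 1)
  out <- NULL
  for (i in seq_len(G)) {
    rest <- setdiff(seq_len(G), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub), G - 1)))
  }
  unname(out)
}

# Permute a fit's class labels (used to align fold refits to the full-data
# model's canonical ordering).
permute_fit_classes <- function(fit, perm) {
  G <- fit$spec$G
  if (identical(perm, seq_len(G))) return(fit)
  fit$alpha <- fit$alpha[perm, , drop = FALSE]
  fit$posterior <- fit$posterior[, perm, drop = FALSE]
  if (G > 1L) {
    eta <- rbind(0, fit$zeta)[perm, , drop = FALSE]
    fit$zeta <- sweep(eta, 2, eta[1, ])[-1, , drop = FALSE]
  }
  inv <- order(perm)
  fit$class_labels <- stats::setNames(inv[fit$class_labels],
                                      names(fit$class_labels))
  fit
}

# Align a refitted model's classes to a reference fit by minimal summed
# squared distance between back-transformed class mean curves on a 13-point
# grid.
align_classes <- function(fit, reference, grid_points = 13) {
  G <- fit$spec$G
  if (G == 1L) return(fit)
  tmax <- min(fit$basis$boundary_knots[2], reference$basis$boundary_knots[2])
  grid <- seq(0, tmax, length.out = grid_points)
  curves <- function(f) {
    tr <- class_trajectories(f, grid, ci = FALSE)
    matrix(tr$mean, nrow = G, byrow = TRUE)
  }
  cf <- curves(fit); cr <- curves(reference)
  best <- NULL; best_d <- Inf
  for (perm in all_permutations(G)) {
    d <- sum((cf[perm, , drop = FALSE] - cr)^2)
    if (d < best_d) { best_d <- d; best <- perm }
  }
  permute_fit_classes(fit, best)
}

#' Cross-validated baseline-only class prediction
#'
#' For each fold, refits the LCMM on the training 90\% — including refitting
#' the Box-Cox transform, spline knots and covariate scaling on training
#' data only — aligns the retrained model's classes to the full-data model's
#' canonical ordering by trajectory matching, and predicts the held-out
#' subjects from baseline data alone. Held-out outcomes after t = 0 are
#' never touched. The hippocampal atrophy z-score is computed once on the
#' full cohort (a baseline covariate; no outcome information).
#'
#' @param cohort A \code{cohort_data}.
#' @param spec An \code{lcmm_spec}.
#' @param folds Fold assignment from [make_folds()].
#' @param full_fit The full-data \code{lcmm_fit} used as the class-alignment
#'   reference.
#' @param n_starts,seed EM controls for the fold refits.
#' @param use_outcome Passed to [predict_class_baseline()].
#' @param ... Passed to [fit_lcmm()].
#' @return List with \code{predictions} (data frame: subject_id, fold,
#'   p_class1..p_classG, predicted), \code{failed_folds}, and per-fold fit
#'   metadata.
#' @export
cross_validate <- function(cohort, spec, folds, full_fit, n_starts = 2,
                           seed = 1, use_outcome = TRUE, ...) {
  b <- cohort$baseline
  if (!"hipp_atrophy_z" %in% names(b)) {
    ok <- stats::complete.cases(b[c("hippocampal_volume", "icv")])
    b$hipp_atrophy_z <- NA_real_
    if (sum(ok) >= 3)
      b$hipp_atrophy_z[ok] <- residualize_and_z(b$hippocampal_volume[ok],
                                                b$icv[ok])
    cohort$baseline <- b
  }
  G <- spec$G
  preds <- list(); meta <- list(); failed <- integer(0)
  for (k in sort(unique(folds))) {
    test_ids <- names(folds)[folds == k]
    train_ids <- setdiff(b$subject_id, test_ids)
    train <- cohort_data(
      cohort$visits[cohort$visits$subject_id %in% train_ids, , drop = FALSE],
      b[b$subject_id %in% train_ids, , drop = FALSE])
    fit_k <- tryCatch(
      suppressWarnings(fit_lcmm(train, spec, n_starts = n_starts,
                                seed = derive_seed(seed, k), ...)),
      error = function(e) NULL)
    if (is.null(fit_k)) { failed <- c(failed, k); next }
    fit_k <- align_classes(fit_k, full_fit)
    p <- predict_class_baseline(fit_k, cohort, subjects = test_ids,
                                use_outcome = use_outcome)
    preds[[as.character(k)]] <- data.frame(
      subject_id = rownames(p), fold = k,
      stats::setNames(as.data.frame(p), paste0("p_class", seq_len(G))),
      predicted = max.col(p, ties.method = "first"))
    meta[[as.character(k)]] <- list(
      loglik = fit_k$loglik, converged = fit_k$converged,
      n_train = length(train_ids))
  }
  if (length(failed))
    warnf("fold(s) %s failed to fit and were excluded",
          paste(failed, collapse = ", "))
  out <- do.call(rbind, preds)
  rownames(out) <- NULL
  list(predictions = out, failed_folds = failed, fold_fits = meta)
}

#' Precision-recall curve and average precision
#'
#' Precision and recall at every distinct score threshold (descending; tied
#' scores are grouped into a single step). The area under the curve is the
#' average-precision estimator: the sum over threshold steps of the recall
#' increment times the precision at that step — step interpolation, which
#' avoids the optimism of linear interpolation in PR space.
#'
#' @param scores Numeric vector (higher = more confidently positive).
#' @param positives Binary vector (1 = positive), same length.
#' @return Object of class \code{pr_curve}: \code{thresholds},
#'   \code{precision}, \code{recall}, \code{auprc}.
#' @export
pr_curve <- function(scores, positives) {
  stopifnot(length(scores) == length(positives))
  positives <- as.integer(positives > 0)
  P <- sum(positives)
  if (P == 0L) stopf("pr_curve: no positive cases, metric undefined")
  if (P == length(positives)) stopf("pr_curve: no negative cases")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- positives[ord]
  last <- which(c(s[-1] != s[-length(s)], TRUE))  # last index of each tied group
  tp <- cumsum(y)[last]
  n_at <- last
  precision <- tp / n_at
  recall <- tp / P
  d_recall <- diff(c(0, recall))
  auprc <- sum(d_recall * precision)
  structure(list(thresholds = s[last], precision = precision,
                 recall = recall, auprc = auprc), class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("<pr_curve> %d thresholds, AUPRC (average precision) = %.4f\n",
              length(x$thresholds), x$auprc))
  invisible(x)
}

wilson_ci <- function(x, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = ctr - hw, upper = ctr + hw)
}

#' Classification performance metrics
#'
#' Accuracy with a Wilson 95\% interval, balanced accuracy (mean per-class
#' recall over classes present in the truth), the confusion matrix, and —
#' when class probabilities are supplied — one-vs-rest AUPRC per class plus
#' the "any decliner vs stable" AUPRC (score \code{1 - p_class1}, positives
#' = any class above 1, following the canonical ordering where class 1 is
#' stable).
#'
#' @param predicted,truth Class vectors on the same subjects (aligned by
#'   names when named, else by position).
#' @param probabilities Optional matrix (subjects x G) of class
#'   probabilities.
#' @param level Confidence level for the accuracy interval.
#' @return List: \code{accuracy}, \code{accuracy_ci}, \code{balanced_accuracy},
#'   \code{confusion}, \code{auprc} (per class), \code{auprc_any_decliner}.
#' @export
classification_metrics <- function(predicted, truth, probabilities = NULL,
                                   level = 0.95) {
  if (!is.null(names(predicted)) && !is.null(names(truth)))
    predicted <- predicted[names(truth)]
  if (length(predicted) != length(truth)) stopf("subject sets differ")
  n <- length(truth)
  acc <- mean(predicted == truth)
  classes <- sort(unique(truth))
  recalls <- vapply(classes, function(g)
    mean(predicted[truth == g] == g), numeric(1))
  confusion <- table(truth = truth, predicted = predicted)
  auprc <- NULL; auprc_any <- NULL
  if (!is.null(probabilities)) {
    probabilities <- rbind(probabilities)
    G <- ncol(probabilities)
    auprc <- vapply(seq_len(G), function(g) {
      pos <- as.integer(truth == g)
      if (sum(pos) %in% c(0L, n)) return(NA_real_)
      pr_curve(probabilities[, g], pos)$auprc
    }, numeric(1))
    pos_any <- as.integer(truth != classes[1])
    if (!sum(pos_any) %in% c(0L, n))
      auprc_any <- pr_curve(1 - probabilities[, 1], pos_any)$auprc
  }
  list(accuracy = acc,
       accuracy_ci = wilson_ci(sum(predicted == truth), n, level),
       balanced_accuracy = mean(recalls),
       per_class_recall = stats::setNames(recalls, classes),
       confusion = confusion, auprc = auprc,
       auprc_any_decliner = auprc_any)
}

#' Agreement between two classifications of the same subjects
#'
#' @param labels_a,labels_b Named class vectors; compared on common
#'   subjects (canonical class alignment is assumed).
#' @return List \code{n_reclassified}, \code{fraction}, \code{n_common}.
#' @export
classification_agreement <- function(labels_a, labels_b) {
  common <- intersect(names(labels_a), names(labels_b))
  if (!length(common)) stopf("no overlapping subjects")
  diffs <- sum(labels_a[common] != labels_b[common])
  list(n_reclassified = diffs, fraction = diffs / length(common),
       n_common = length(common))
}
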