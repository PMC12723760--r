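# Classification tree (CART) for post-hoc characterization of latent
# classes from baseline variables: greedy Gini splitting on midpoint
# thresholds, complexity-parameter pre-pruning, 10-fold CV tuning, and
# primary-split impurity importance (no surrogate splits: inputs are
# complete-case, and surrogate credit inflates correlated predictors).

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# Best threshold for one numeric feature: maximal n-weighted Gini decrease,
# ties broken toward the lower threshold (first maximum in sorted order).
best_split_numeric <- function(x, y, G, min_bucket) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  cum <- sapply(seq_len(G), function(g) cumsum(ys == g))
  cum <- matrix(cum, ncol = G)
  total <- cum[n, ]
  i <- seq_len(n - 1)
  valid <- xs[i] < xs[i + 1] & i >= min_bucket & (n - i) >= min_bucket
  if (!any(valid)) return(NULL)
  i <- i[valid]
  nl <- i; nr <- n - i
  gl <- 1 - rowSums((cum[i, , drop = FALSE] / nl)^2)
  gr <- 1 - rowSums((sweep(cum[i, , drop = FALSE], 2, total, "-") / -nr)^2)
  g_node <- gini_impurity(total)
  dec <- n * g_node - (nl * gl + nr * gr)
  b <- which.max(dec)
  list(decrease = dec[b], threshold = (xs[i[b]] + xs[i[b] + 1]) / 2)
}

#' Grow a classification tree
#'
#' Recursive greedy Gini splitting. At each node the best
#' (variable, threshold) pair maximizes the n-weighted impurity decrease;
#' ties are broken by variable order in \code{features}, then by the lower
#' threshold. Thresholds are midpoints between consecutive distinct sorted
#' values (rows with value < threshold go left). A split is kept only if
#' the overall impurity decrease — the n-weighted decrease divided by the
#' total sample size — is at least \code{cp} times the root impurity, the
#' node has at least \code{min_split} rows, and both children have at least
#' \code{min_bucket}.
#'
#' @param features Data frame of numeric features (no missing values).
#' @param labels Class vector (coerced to factor).
#' @param cp Complexity parameter.
#' @param min_split,min_bucket Minimum node size to attempt a split /
#'   minimum child size.
#' @return An object of class \code{cart_tree} with the nested \code{root}
#'   node, raw \code{importance}, and the class \code{levels}.
#' @export
grow_tree <- function(features, labels, cp = 0.01, min_split = 20,
                      min_bucket = 7) {
  features <- as.data.frame(features)
  if (anyNA(features)) stopf("grow_tree requires complete-case features")
  y <- factor(labels)
  lev <- levels(y)
  yi <- as.integer(y)
  G <- length(lev)
  n_total <- length(yi)
  root_counts <- tabulate(yi, G)
  g_root <- gini_impurity(root_counts)
  importance <- stats::setNames(numeric(ncol(features)), names(features))

  grow <- function(idx) {
    counts <- tabulate(yi[idx], G)
    node <- list(n = length(idx), class_counts = counts,
                 predicted = which.max(counts),
                 impurity = gini_impurity(counts))
    if (length(idx) < min_split || node$impurity == 0 || g_root == 0)
      return(node)
    best <- NULL
    for (v in names(features)) {
      s <- best_split_numeric(features[[v]][idx], yi[idx], G, min_bucket)
      if (!is.null(s) && (is.null(best) || s$decrease > best$decrease)) {
        best <- s; best$variable <- v
      }
    }
    if (is.null(best) || best$decrease / n_total < cp * g_root)
      return(node)
    left_idx <- idx[features[[best$variable]][idx] < best$threshold]
    right_idx <- setdiff(idx, left_idx)
    importance[best$variable] <<- importance[best$variable] +
      best$decrease / n_total
    node$split_variable <- best$variable
    node$split_threshold <- best$threshold
    node$left <- grow(left_idx)
    node$right <- grow(right_idx)
    node
  }

  root <- grow(seq_len(n_total))
  structure(list(root = root, cp = cp, min_split = min_split,
                 min_bucket = min_bucket, importance = importance,
                 levels = lev, n = n_total, variables = names(features)),
            class = "cart_tree")
}

#' Predict classes from a fitted tree
#'
#' @param object A \code{cart_tree}.
#' @param newdata Data frame with the training feature columns.
#' @param type \code{"class"} (factor) or \code{"prob"} (matrix of leaf
#'   class proportions).
#' @param ... Unused.
#' @export
predict.cart_tree <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  n <- nrow(newdata)
  G <- length(object$levels)
  prob <- matrix(NA_real_, n, G)
  route <- function(node, idx) {
    if (is.null(node$split_variable)) {
      prob[idx, ] <<- matrix(node$class_counts / node$n, length(idx), G,
                             byrow = TRUE)
      return(invisible())
    }
    left <- newdata[[node$split_variable]][idx] < node$split_threshold
    if (any(left)) route(node$left, idx[left])
    if (any(!left)) route(node$right, idx[!left])
  }
  route(object$root, seq_len(n))
  if (type == "prob") {
    colnames(prob) <- object$levels
    return(prob)
  }
  factor(object$levels[max.col(prob, ties.method = "first")],
         levels = object$levels)
}

#' Impurity-based variable importance
#'
#' Per variable, the sum over nodes split on it of the node-share-weighted
#' Gini decrease, normalized to percentages summing to 100. A single-leaf
#' tree returns an empty table.
#'
#' @param model A \code{cart_tree}.
#' @return Named percentage vector (descending), or empty.
#' @export
variable_importance <- function(model) {
  imp <- model$importance[model$importance > 0]
  if (!length(imp)) return(stats::setNames(numeric(0), character(0)))
  sort(100 * imp / sum(imp), decreasing = TRUE)
}

#' Tune the complexity parameter by stratified cross-validation
#'
#' Class-stratified K folds; per \code{cp}, the mean cross-validated
#' accuracy and the mean and standard error (sample SD of fold values /
#' sqrt(K)) of balanced accuracy. The selected \code{cp} maximizes raw CV
#' accuracy; ties go to the larger \code{cp} (simpler tree). The final tree
#' is refit on all data at the selected \code{cp}.
#'
#' @param features,labels As in [grow_tree()].
#' @param cp_grid Candidate complexity parameters.
#' @param K Number of folds.
#' @param seed Integer seed for fold assignment.
#' @param min_split,min_bucket Passed to [grow_tree()].
#' @return List: \code{best_cp}, \code{model} (refit \code{cart_tree} with
#'   \code{cv_accuracy} and \code{cv_balanced_accuracy} attached),
#'   \code{cv_table}.
#' @export
tune_tree <- function(features, labels, cp_grid = c(0.0005, 0.001, 0.002,
                                                    0.005, 0.01, 0.02, 0.05),
                      K = 10, seed = 1, min_split = 20, min_bucket = 7) {
  if (!length(cp_grid)) stopf("cp_grid is empty")
  features <- as.data.frame(features)
  y <- factor(labels)
  ids <- sprintf("r%06d", seq_along(y))
  folds <- make_folds(stats::setNames(as.character(y), ids),
                      stats::setNames(rep(1, length(y)), ids), K = K,
                      seed = seed)
  folds <- folds[ids]
  rows <- list()
  for (cp in sort(cp_grid)) {
    accs <- baccs <- numeric(0)
    for (k in sort(unique(folds))) {
      te <- which(folds == k); tr <- which(folds != k)
      if (!length(te) || length(unique(y[tr])) < 2) next
      tree <- grow_tree(features[tr, , drop = FALSE], y[tr], cp = cp,
                        min_split = min_split, min_bucket = min_bucket)
      pred <- predict(tree, features[te, , drop = FALSE])
      m <- classification_metrics(as.character(pred), as.character(y[te]))
      accs <- c(accs, m$accuracy)
      baccs <- c(baccs, m$balanced_accuracy)
    }
    rows[[as.character(cp)]] <- data.frame(
      cp = cp, cv_accuracy = mean(accs),
      cv_balanced_accuracy = mean(baccs),
      cv_balanced_accuracy_se = stats::sd(baccs) / sqrt(length(baccs)))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  best <- max(tab$cp[tab$cv_accuracy >= max(tab$cv_accuracy) - 1e-12])
  model <- grow_tree(features, y, cp = best, min_split = min_split,
                     min_bucket = min_bucket)
  model$cv_accuracy <- tab$cv_accuracy[tab$cp == best]
  model$cv_balanced_accuracy <- c(
    mean = tab$cv_balanced_accuracy[tab$cp == best],
    se = tab$cv_balanced_accuracy_se[tab$cp == best])
  list(best_cp = best, model = model, cv_table = tab)
}

#' @export
print.cart_tree <- function(x, ...) {
  cat(sprintf("<cart_tree> n = %d, cp = %g, classes: %s\n", x$n, x$cp,
              paste(x$levels, collapse = ", ")))
  rec <- function(node, depth, prefix) {
    pad <- strrep("  ", depth)
    if (is.null(node$split_variable)) {
      cat(sprintf("%s%s leaf: %s (n = %d, [%s])\n", pad, prefix,
                  x$levels[node$predicted], node$n,
                  paste(node$class_counts, collapse = "/")))
    } else {
      cat(sprintf("%s%s %s < %.4g? (n = %d)\n", pad, prefix,
                  node$split_variable, node$split_threshold, node$n))
      rec(node$left, depth + 1, "yes:")
      rec(node$right, depth + 1, "no: ")
    }
  }
  rec(x$root, 0, "")
  invisible(x)
}

#' Serialize a tree to JSON
#'
#' @param model A \code{cart_tree}.
#' @param path JSON path.
#' @export
tree_to_json <- function(model, path) {
  strip <- function(node) {
    out <- node[c("n", "class_counts", "predicted", "impurity")]
    if (!is.null(node$split_variable)) {
      out$split_variable <- node$split_variable
      out$split_threshold <- node$split_threshold
      out$left <- strip(node$left)
      out$right <- strip(node$right)
    }
    out
  }
  rec <- list(levels = model$levels, cp = model$cp,
              importance = as.list(variable_importance(model)),
              root = strip(model$root))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
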