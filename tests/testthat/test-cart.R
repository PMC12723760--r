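test_that("Gini impurity closed forms", {
  expect_equal(gini_impurity(c(50, 50)), 0.5)
  expect_equal(gini_impurity(c(100, 0)), 0)
  expect_equal(gini_impurity(c(1, 1, 1)), 1 - 3 * (1 / 3)^2)
  expect_equal(gini_impurity(c(0, 0)), 0)
})

test_that("pure labels give a single leaf with empty importance", {
  tree <- grow_tree(data.frame(x = rnorm(50)), rep("a", 50))
  expect_null(tree$root$split_variable)
  expect_length(variable_importance(tree), 0)
})

test_that("a perfectly separating feature yields a depth-1 tree", {
  set.seed(21)
  x <- runif(100)
  y <- ifelse(x < 0.5, "neg", "pos")
  tree <- grow_tree(data.frame(noise = rnorm(100), x = x), y, cp = 0.01)
  expect_identical(tree$root$split_variable, "x")
  expect_gt(tree$root$split_threshold, 0.49)
  expect_lt(tree$root$split_threshold, 0.51)
  expect_null(tree$root$left$split_variable)
  expect_null(tree$root$right$split_variable)
  expect_equal(mean(predict(tree, data.frame(noise = 0, x = x)) == y), 1)
  imp <- variable_importance(tree)
  expect_equal(unname(imp["x"]), 100)
})

test_that("importance percentages sum to 100 and split by variable order", {
  set.seed(22)
  n <- 400
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- factor((x1 > 0) + (x2 > 0.5))
  tree <- grow_tree(data.frame(x1 = x1, x2 = x2), y, cp = 0.001)
  imp <- variable_importance(tree)
  expect_equal(sum(imp), 100, tolerance = 1e-6)
  expect_true(all(imp >= 0))

  # duplicating a feature: ties break to the first column, combined
  # importance of the duplicates equals the original's
  tree2 <- grow_tree(data.frame(x1 = x1, x1dup = x1, x2 = x2), y,
                     cp = 0.001)
  imp2 <- variable_importance(tree2)
  tot <- sum(imp2[grep("^x1", names(imp2))])
  expect_equal(tot, unname(imp["x1"]), tolerance = 1e-8)
  expect_true(!"x1dup" %in% names(imp2) || imp2["x1dup"] == 0)
})

test_that("predictions are invariant to monotone feature transforms", {
  set.seed(23)
  n <- 300
  x <- rnorm(n); z <- rnorm(n)
  y <- factor(x + 0.5 * z + rnorm(n, 0, 0.5) > 0)
  t1 <- grow_tree(data.frame(x = x, z = z), y, cp = 0.005)
  t2 <- grow_tree(data.frame(x = exp(x), z = z), y, cp = 0.005)
  p1 <- predict(t1, data.frame(x = x, z = z))
  p2 <- predict(t2, data.frame(x = exp(x), z = z))
  expect_identical(as.character(p1), as.character(p2))
})

test_that("training accuracy is non-increasing in cp", {
  set.seed(24)
  n <- 500
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- factor(X$a + rnorm(n, 0, 0.8) > 0)
  accs <- vapply(c(0.0005, 0.005, 0.05, 0.5), function(cp) {
    tr <- grow_tree(X, y, cp = cp)
    mean(predict(tr, X) == y)
  }, numeric(1))
  expect_true(all(diff(accs) <= 1e-12))
})

test_that("min_bucket and min_split constraints hold everywhere", {
  set.seed(25)
  X <- data.frame(x = rnorm(200))
  y <- factor(X$x + rnorm(200, 0, 0.5) > 0)
  tree <- grow_tree(X, y, cp = 0.0005, min_split = 20, min_bucket = 7)
  check <- function(node) {
    if (is.null(node$split_variable)) return(invisible())
    expect_gte(node$n, 20)
    expect_gte(node$left$n, 7)
    expect_gte(node$right$n, 7)
    expect_equal(node$left$class_counts + node$right$class_counts,
                 node$class_counts)
    check(node$left); check(node$right)
  }
  check(tree$root)
})

test_that("tree tuning selects sensible complexity and reports CV spread", {
  set.seed(26)
  n <- 300
  X <- data.frame(x = rnorm(n), junk = rnorm(n))
  y <- factor(ifelse(X$x + rnorm(n, 0, 0.3) < 0, "lo", "hi"))  # near-separable
  tt <- tune_tree(X, y, cp_grid = c(0.001, 0.01, 1), K = 5, seed = 3)
  expect_lt(tt$best_cp, 1)
  expect_gt(max(tt$cv_table$cv_accuracy), 0.85)

  # cp = 1 on noisy data: no split survives, CV accuracy ~ prevalence
  y2 <- factor(rbinom(n, 1, 0.7))
  t2 <- tune_tree(X, y2, cp_grid = 1, K = 5, seed = 4)
  expect_null(t2$model$root$split_variable)
  prev <- max(table(y2)) / n
  expect_lt(abs(t2$cv_table$cv_accuracy - prev), 0.02)
  expect_true(is.finite(t2$cv_table$cv_balanced_accuracy_se))

  # ties in CV accuracy go to the larger cp
  t3 <- tune_tree(X, y, cp_grid = c(0.001, 0.002), K = 5, seed = 5)
  expect_equal(t3$best_cp,
               max(t3$cv_table$cp[t3$cv_table$cv_accuracy >=
                                    max(t3$cv_table$cv_accuracy) - 1e-12]))
})

test_that("splits agree with an independent recursive-partitioning fitter", {
  skip_if_not_installed("rpart")
  set.seed(27)
  n <- 400
  X <- data.frame(u = rnorm(n), v = rnorm(n))
  y <- factor(ifelse(X$u + 0.3 * X$v + rnorm(n, 0, 0.6) > 0, "a", "b"))
  ours <- grow_tree(X, y, cp = 0.01)
  ref <- rpart::rpart(y ~ u + v, data = cbind(X, y = y), method = "class",
                      control = rpart::rpart.control(
                        cp = 0.01, minsplit = 20, minbucket = 7,
                        maxsurrogate = 0, usesurrogate = 0, xval = 0))
  expect_identical(ours$root$split_variable,
                   as.character(ref$frame$var[1]))
  expect_equal(ours$root$split_threshold,
               unname(ref$splits[1, "index"]), tolerance = 1e-8)
  acc_ours <- mean(predict(ours, X) == y)
  acc_ref <- mean(predict(ref, X, type = "class") == y)
  expect_lt(abs(acc_ours - acc_ref), 0.03)
})

test_that("biomarker-driven classes rank P-tau217 and baseline PACC highly", {
  preset <- preset_a4learn_like(derive_n = 8000)
  for (seed in c(101, 102)) {
    sim <- simulate_cohort(preset, n = 700, seed = seed)
    feats <- cogmix:::tree_features(sim$cohort)
    ok <- complete.cases(feats)
    tree <- grow_tree(feats[ok, ], sim$true_class[rownames(feats)[ok]],
                      cp = 0.003)
    imp <- variable_importance(tree)
    top <- names(imp)[1:3]
    expect_true("ptau217" %in% top || "pacc_baseline" %in% top)
  }
})

test_that("trees serialize to JSON with nested nodes", {
  set.seed(28)
  X <- data.frame(x = rnorm(100))
  y <- factor(X$x > 0)
  tree <- grow_tree(X, y, cp = 0.01)
  p <- withr::local_tempfile(fileext = ".json")
  tree_to_json(tree, p)
  rec <- jsonlite::read_json(p)
  expect_equal(rec$root$n, 100)
  expect_true(!is.null(rec$root$split_variable))
})
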