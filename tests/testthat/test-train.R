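# Losses, class weighting, splitting protocol, the training loop and the
# metric panel.

test_that("class weights are balanced inverse frequencies", {
  expect_equal(unname(class_weights(rep(c(0, 1), 50))), c(1, 1))
  w <- class_weights(c(rep(1, 10), rep(0, 90)))
  expect_equal(unname(w), c(100 / (2 * 90), 5))
  # invariant to label order
  expect_equal(class_weights(sample(c(rep(1, 10), rep(0, 90)))), w)
  expect_error(class_weights(rep(1, 5)), "both classes")
})

test_that("losses match their closed forms", {
  y <- rbind(c(1, 0), c(0, 1))
  # perfect predictions: zero up to the log clamp
  expect_lt(main_loss(y, y), 1e-10)
  # uniform binary prediction: ln 2
  expect_equal(main_loss(matrix(0.5, 2, 2), y), log(2))
  # hand case with weights (2, 1)
  p <- rbind(c(0.8, 0.2), c(0.4, 0.6))
  expect_equal(main_loss(p, y, c(2, 1)), -(2 * log(0.8) + log(0.6)) / 2)
  # auxiliary loss: softmax cross-entropy
  expect_lt(aux_loss(rbind(c(50, -50), c(-50, 50)), y), 1e-10)
  expect_equal(aux_loss(matrix(0, 2, 2), y), log(2))
  lg <- rbind(c(1, -1), c(0.5, 2))
  byhand <- -(log(exp(1) / (exp(1) + exp(-1))) * 3 +
                log(exp(2) / (exp(0.5) + exp(2)))) / 2
  expect_equal(aux_loss(lg, y, c(3, 1)), byhand)
  # overall loss: main + alpha aux_s + beta aux_n at the defaults (2, 1)
  expect_equal(overall_loss(0.5, 0.2, 0.3, train_config()), 1.2)
  expect_equal(overall_loss(0.5, 0.2, 0.3, train_config(alpha = 0, beta = 0)), 0.5)
  a <- runif(3)
  expect_equal(overall_loss(a[1], a[2], a[3], train_config()),
               a[1] + 2 * a[2] + a[3])
})

test_that("stratified splits preserve prevalence and partition the data", {
  set.seed(2)
  labels <- rbinom(500, 1, 0.12)
  sp <- stratified_split(labels, seed = 9)
  expect_identical(sort(c(sp$train, sp$val, sp$test)), seq_along(labels))
  for (part in sp)
    expect_lte(abs(sum(labels[part]) - length(part) * mean(labels)), 1)
  expect_identical(stratified_split(labels, seed = 9), sp)
  expect_false(identical(stratified_split(labels, seed = 10), sp))
  folds <- stratified_folds(labels, k = 5, seed = 9)
  expect_identical(sort(unlist(folds)), seq_along(labels))
  glob <- mean(labels)
  for (fd in folds)
    expect_lte(abs(sum(labels[fd]) - glob * length(fd)), 1)
  expect_identical(stratified_folds(labels, k = 5, seed = 9), folds)
})

test_that("training is deterministic, improves and early-stops", {
  set.seed(5)
  n <- 80
  x <- matrix(rnorm(n * 2), n, 2)
  y <- as.integer(x[, 1] + x[, 2] > 0)
  x <- x + 0.5 * y                      # separable-ish
  inputs <- list(structured = x)
  idx <- 1:60; vidx <- 61:80
  build <- function() build_fusion_model(inputs, binary_frame(),
                                         kinds = "structured",
                                         n_prototypes = 3, train_idx = idx,
                                         seed = 4)
  cfg <- train_config(max_epochs = 8, seed = 11, use_class_weights = FALSE)
  f1 <- train_model(build(), inputs, y, cfg, idx, vidx)
  f2 <- train_model(build(), inputs, y, cfg, idx, vidx)
  expect_identical(f1$history, f2$history)
  expect_lt(utils::tail(f1$history$train_loss, 1), f1$history$train_loss[1])
  # patience 0: stops at the first epoch without sufficient improvement
  noisy <- list(structured = matrix(rnorm(n * 2), n, 2))
  f3 <- train_model(build_fusion_model(noisy, binary_frame(),
                                       kinds = "structured", n_prototypes = 3,
                                       train_idx = idx, seed = 4),
                    noisy, sample(y), train_config(max_epochs = 50, patience = 0,
                                                   seed = 2), idx, vidx)
  expect_lt(nrow(f3$history), 50L)
  # the run ends exactly one epoch after the last validation improvement
  vl <- f3$history$val_loss
  best <- cummin(vl)
  expect_false(vl[length(vl)] < best[length(vl) - 1] - 1e-4)
})

test_that("the confusion fixture reproduces the hand-derived panel", {
  p <- c(rep(0.9, 30), rep(0.9, 10), rep(0.1, 20), rep(0.1, 40))
  o <- c(rep(1, 30), rep(0, 10), rep(1, 20), rep(0, 40))
  m <- compute_metrics(p, o)
  expect_equal(unname(m[c("tp", "fp", "fn", "tn")]), c(30, 10, 20, 40))
  expect_equal(unname(m["precision"]), 0.75)
  expect_equal(unname(m["recall"]), 0.60)
  expect_equal(unname(m["specificity"]), 0.80)
  expect_equal(unname(m["npv"]), 2 / 3)
  expect_equal(unname(m["bacc"]), 0.70)
  expect_equal(unname(m["f1"]), 2 / 3)
})

test_that("reliability metrics match their definitions", {
  # perfect forecasts
  m <- compute_metrics(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unname(m["brier"]), 0)
  expect_lt(unname(m["nll"]), 1e-10)
  # hand Brier fixture: ((0.8-1)^2 + (0.3-0)^2)/2
  m2 <- compute_metrics(c(0.8, 0.3), c(1, 0))
  expect_equal(unname(m2["brier"]), 0.065)
  expect_equal(unname(m2["nll"]), -(log(0.8) + log(0.7)) / 2)
})

test_that("degenerate confusions report NA, not zero", {
  m <- compute_metrics(c(0.1, 0.2, 0.3), c(0, 0, 1))  # nothing predicted positive
  expect_true(is.na(m["precision"]))
  expect_true(is.na(m["f1"]))
  expect_equal(unname(m["recall"]), 0)
})

test_that("BACC is the mean of recall and specificity on random confusions", {
  set.seed(3)
  for (i in 1:30) {
    n <- 200
    o <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(o)) < 2) next
    p <- runif(n)
    m <- compute_metrics(p, o)
    expect_equal(unname(m["bacc"]), unname((m["recall"] + m["specificity"]) / 2))
  }
})

test_that("ranking metrics agree with independent formulations", {
  set.seed(8)
  o <- rbinom(300, 1, 0.3)
  p <- runif(300)
  m <- compute_metrics(p, o)
  # AUROC as the Mann-Whitney U statistic
  r <- rank(p)
  u <- (sum(r[o == 1]) - sum(o) * (sum(o) + 1) / 2) / (sum(o) * sum(o == 0))
  expect_equal(unname(m["auroc"]), u, tolerance = 1e-12)
  # AUPRC as the direct sum over positive ranks (no ties here)
  ord <- order(p, decreasing = TRUE)
  os <- o[ord]
  ap <- sum((cumsum(os) / seq_along(os))[os == 1]) / sum(os)
  expect_equal(unname(m["auprc"]), ap, tolerance = 1e-12)
  # a random scorer sits near chance level
  set.seed(12)
  o2 <- rbinom(2000, 1, 0.5)
  m2 <- compute_metrics(runif(2000), o2)
  expect_lt(abs(m2["auroc"] - 0.5), 0.05)
})

test_that("fold reports aggregate with mean and standard error", {
  rows <- list(c(precision = 0.5, recall = 0.6, specificity = 0.7, npv = 0.8,
                 bacc = 0.65, f1 = 0.55, auroc = 0.8, auprc = 0.5,
                 brier = 0.1, nll = 0.3, tp = 1, fp = 1, fn = 1, tn = 1),
               c(precision = 0.7, recall = 0.8, specificity = 0.9, npv = 0.6,
                 bacc = 0.85, f1 = 0.75, auroc = 0.9, auprc = 0.7,
                 brier = 0.2, nll = 0.5, tp = 1, fp = 1, fn = 1, tn = 1))
  rep <- eval_report(rows)
  expect_identical(rep$fold, c("1", "2", "mean", "se"))
  expect_equal(rep$precision[3], 0.6)
  expect_equal(rep$precision[4], stats::sd(c(0.5, 0.7)) / sqrt(2))
  expect_false("tp" %in% names(rep))
})

test_that("cross-validation runs the full leak-free protocol", {
  cohort <- tiny_cohort(n = 120, seed = 6)
  cfg <- train_config(max_epochs = 2, n_folds = 2, seed = 3)
  cv <- run_cv(cohort, cfg, fusion_spec("evidential"), n_prototypes = 3,
               text_dim = 32)
  expect_identical(sort(unlist(cv$folds)), seq_along(cohort$labels))
  expect_equal(nrow(cv$report), 4L)    # 2 folds + mean + se
  expect_true(all(cv$report$auroc >= 0 & cv$report$auroc <= 1, na.rm = TRUE))
  expect_length(cv$histories, 2L)
})
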