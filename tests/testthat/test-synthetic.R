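# The synthetic cohort generator and the preprocessing/imputation pipeline.

test_that("the generator is deterministic and hits its prevalence", {
  c1 <- tiny_cohort(n = 150, seed = 9)
  c2 <- tiny_cohort(n = 150, seed = 9)
  expect_identical(c1$structured, c2$structured)
  expect_identical(c1$notes, c2$notes)
  expect_identical(c1$labels, c2$labels)
  expect_false(identical(tiny_cohort(n = 150, seed = 10)$labels, c1$labels))
  # positives within the binomial 99% interval at the configured rate
  big <- generate_cohort(cohort_spec(n_patients = 10000, note_types = "Nursing",
                                     note_length = 3, seed = 2))
  ci <- stats::qbinom(c(0.005, 0.995), 10000, 0.12)
  expect_gte(sum(big$labels), ci[1])
  expect_lte(sum(big$labels), ci[2])
})

test_that("zero effect sizes leave downstream discrimination at chance", {
  cohort <- generate_cohort(cohort_spec(
    n_patients = 1500, effect_numeric = 0, effect_binary = 0,
    token_rate_pos = 0.02, note_types = "Nursing", note_length = 5, seed = 5))
  sp <- stratified_split(cohort$labels, seed = 5)
  pp <- preprocess_structured(cohort$structured, cohort$col_tags, sp$train)
  df <- data.frame(y = cohort$labels, pp$matrix)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df[sp$train, ],
                                     family = stats::binomial))
  p <- suppressWarnings(stats::predict(fit, df[sp$test, ], type = "response"))
  auroc <- compute_metrics(p, cohort$labels[sp$test])["auroc"]
  expect_lt(abs(auroc - 0.5), 0.08)
})

test_that("single-modality discrimination rises with the effect size", {
  aurocs <- vapply(c(0.3, 0.8, 1.5), function(eff) {
    cohort <- generate_cohort(cohort_spec(
      n_patients = 2000, effect_numeric = eff, effect_binary = 0,
      modality_correlation = 1, weak_fraction = 0,
      note_types = "Nursing", note_length = 3, seed = 17))
    sp <- stratified_split(cohort$labels, seed = 17)
    pp <- preprocess_structured(cohort$structured, cohort$col_tags, sp$train)
    df <- data.frame(y = cohort$labels, pp$matrix)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df[sp$train, ],
                                       family = stats::binomial))
    p <- suppressWarnings(stats::predict(fit, df[sp$test, ], type = "response"))
    unname(compute_metrics(p, cohort$labels[sp$test])["auroc"])
  }, 0)
  expect_true(all(diff(aurocs) > 0))
})

test_that("structured preprocessing follows the stated rules", {
  tab <- data.frame(
    mostly_missing = c(NA, NA, NA, NA, NA, NA, 1, 2, 3, 4),  # 60% missing
    num = c(1, 2, NA, 100, 5, 6, 7, 8, 9, 10),
    bin = c(0, 1, NA, 1, 1, 0, 1, 1, 0, 1),
    cat = c("a", "b", "b", NA, "c", "a", "b", "b", "a", "c"),
    stringsAsFactors = FALSE)
  pp <- preprocess_structured(tab, train_idx = 1:10)
  expect_identical(pp$dropped, "mostly_missing")
  # median imputation: median(1,2,100,5,...,10) with NA removed
  expect_equal(pp$stats$num$impute, stats::median(tab$num, na.rm = TRUE))
  # z-normalization: training mean 0, sd 1
  expect_equal(mean(pp$matrix[, "num"]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(pp$matrix[, "num"]), 1, tolerance = 1e-12)
  # binary stays one column, mode-imputed
  expect_true("bin" %in% colnames(pp$matrix))
  expect_equal(unname(pp$matrix[3, "bin"]), 1)   # mode of the training values
  # character categorical one-hot encoded over its levels
  expect_true(all(c("cat=a", "cat=b", "cat=c") %in% colnames(pp$matrix)))
  expect_equal(unname(pp$matrix[4, "cat=b"]), 1) # mode-imputed then one-hot
  expect_equal(rowSums(pp$matrix[, c("cat=a", "cat=b", "cat=c")]), rep(1, 10))
  # the spec'd tiny median example: (1, 2, missing, 100) -> 2
  tiny <- preprocess_structured(data.frame(x = c(1, 2, NA, 100)))
  expect_equal(tiny$stats$x$impute, 2)
})

test_that("preprocessing statistics never leak from held-out rows", {
  cohort <- tiny_cohort(n = 60, seed = 3)
  train_idx <- 1:40
  pp1 <- preprocess_structured(cohort$structured, cohort$col_tags, train_idx)
  poisoned <- cohort$structured
  poisoned[41:60, ] <- poisoned[41:60, ] * 0 + 1e6
  pp2 <- preprocess_structured(poisoned, cohort$col_tags, train_idx)
  expect_equal(pp1$matrix[train_idx, ], pp2$matrix[train_idx, ])
  # same property for the imputation strategies
  for (st in c("mean", "median", "knn", "iterative")) {
    i1 <- impute_missing(cohort$structured[, 1:4], st, train_idx)
    i2 <- impute_missing(poisoned[, 1:4], st, train_idx)
    expect_equal(i1[train_idx, ], i2[train_idx, ], tolerance = 1e-8)
  }
})

test_that("imputation strategies match their oracles", {
  # untouched when complete
  full <- data.frame(a = 1:4, b = 4:1)
  expect_identical(impute_missing(full, "knn"), full)
  # mean vs median on a skewed fixture
  sk <- data.frame(x = c(1, 1, 1, 100, NA))
  expect_equal(impute_missing(sk, "mean")$x[5], 25.75)
  expect_equal(impute_missing(sk, "median")$x[5], 1)
  # knn: an exact-duplicate donor row supplies its value
  kn <- data.frame(a = c(1, 1, 5, 9, 3), b = c(2, 2, 6, 1, 8),
                   c = c(7, NA, 0, 4, 2))
  expect_equal(impute_missing(kn, "knn")$c[2], 7)
  # iterative imputation recovers an exact linear dependency
  set.seed(4)
  a <- rnorm(30)
  it <- data.frame(a = a, b = 2 * a + 1)
  it$b[c(3, 11)] <- NA
  out <- impute_missing(it, "iterative")
  expect_equal(out$b[c(3, 11)], 2 * a[c(3, 11)] + 1, tolerance = 1e-6)
  expect_error(impute_missing(sk, "hotdeck"), "arg")
})

test_that("note preprocessing prefixes, orders, joins and pads", {
  recs <- data.frame(
    patient_id = c("p1", "p1", "p1", "p2"),
    note_type = c("Physician", "Nursing", "Radiology", "Nursing"),
    text = c("needs review", "pt stable", "clear lungs", "resting"),
    stringsAsFactors = FALSE)
  out <- preprocess_notes(recs, patient_ids = c("p1", "p2", "p3"),
                          max_tokens = 12)
  expect_match(out$text[["p1"]], "^Nursing: pt stable\n")
  expect_identical(out$text[["p1"]],
                   "Nursing: pt stable\nPhysician: needs review\nRadiology: clear lungs")
  expect_identical(out$tokens[["p1"]][1:3], c("nursing:", "pt", "stable"))
  expect_length(out$tokens[["p1"]], 12L)
  expect_identical(out$tokens[["p1"]][10:12], rep("<pad>", 3))
  # truncation to exactly the limit
  long <- data.frame(patient_id = "p9", note_type = "Nursing",
                     text = paste(rep("tok", 600), collapse = " "))
  lt <- preprocess_notes(long, max_tokens = 512)
  expect_length(lt$tokens[["p9"]], 512L)
  expect_false("<pad>" %in% lt$tokens[["p9"]])
  # a patient without notes yields all padding
  expect_identical(out$tokens[["p3"]], rep("<pad>", 12L))
})

test_that("prolonged-stay labels use a strict 7-day boundary", {
  expect_identical(label_plos(c(1, 8, 7, 30)), c(0L, 1L, 0L, 1L))
  expect_identical(label_plos(7.0), 0L)
  expect_identical(label_plos(7.01), 1L)
  expect_error(label_plos(-1))
  # the plos task derives its labels from the generated stays
  cohort <- generate_cohort(cohort_spec(n_patients = 80, task = "plos",
                                        note_types = "Nursing",
                                        note_length = 3, seed = 12))
  expect_identical(cohort$labels, label_plos(cohort$los_days))
})

test_that("cohorts round-trip through their plain-text file formats", {
  cohort <- tiny_cohort(n = 25, seed = 13)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_true(all(file.exists(file.path(dir, c("structured.csv", "col_tags.json",
                                               "notes.jsonl", "labels.csv")))))
  back <- read_cohort(dir)
  expect_equal(back$structured, cohort$structured, tolerance = 1e-12)
  expect_identical(back$labels, cohort$labels)
  expect_identical(back$notes$text, cohort$notes$text)
  expect_identical(back$col_tags$source, cohort$col_tags$source)
})
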