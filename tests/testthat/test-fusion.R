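# Model assembly: evidence fusion, the full forward pass, baseline fusion
# strategies and the data-partitioning settings.

test_that("evidence fusion is a Dempster fold with neutral vacuous inputs", {
  set.seed(3)
  f <- binary_frame()
  m <- rand_simple_mass(f)
  expect_identical(fuse_evidence(list(m)), m)
  r <- fuse_evidence(list(m, vacuous_mass(f)))
  expect_equal(r$singletons, m$singletons, tolerance = 1e-12)
  # K = 3 equals the power-set oracle
  ms <- replicate(3, rand_simple_mass(f), simplify = FALSE)
  got <- as_general_mass(fuse_evidence(ms))
  oracle <- Reduce(combine_masses, lapply(ms, as_general_mass))
  expect_equal(got$masses[match(oracle$keys, got$keys)], oracle$masses,
               tolerance = 1e-10)
})

test_that("agreeing confident modalities concentrate the decision", {
  f <- binary_frame()
  m <- simple_mass(f, c(0, 0.9), 0.1)
  p <- pignistic(fuse_evidence(list(m, m)))
  expect_gt(unname(p["positive"]), 0.9)
  # both vacuous: uniform
  pv <- pignistic(fuse_evidence(list(vacuous_mass(f), vacuous_mass(f))))
  expect_equal(unname(pv), c(0.5, 0.5))
})

test_that("fusing agreeing one-sided evidence never weakens the favored class", {
  # two simple-support masses for the positive class: fused support is
  # a + b - ab, so the pignistic probability can only grow
  set.seed(11)
  f <- binary_frame()
  for (i in 1:50) {
    a <- stats::runif(1); b <- stats::runif(1)
    m1 <- simple_mass(f, c(0, a), 1 - a)
    m2 <- simple_mass(f, c(0, b), 1 - b)
    p <- pignistic(fuse_evidence(list(m1, m2)))["positive"]
    expect_gte(unname(p), max(pignistic(m1)["positive"],
                              pignistic(m2)["positive"]) - 1e-12)
  }
})

test_that("conflict raises the fused ignorance share versus agreement", {
  f <- binary_frame()
  m1 <- simple_mass(f, c(0.6, 0), 0.4)
  agree <- fuse_evidence(list(m1, simple_mass(f, c(0.5, 0), 0.5)))
  clash <- fuse_evidence(list(m1, simple_mass(f, c(0, 0.5), 0.5)))
  expect_gt(clash$ignorance, agree$ignorance)
})

test_that("the model graph reproduces the eager module composition", {
  tm <- tiny_model(seed = 5)
  fw <- model_forward(tm$model, tm$inputs)
  f <- tm$model$frame
  for (k in 1:2) {
    b <- tm$model$bundles[[k]]
    feats <- encode_structured(tm$inputs[[k]], b$encoder)
    expect_equal(fw$masses[[k]], enn_forward(feats, b$em_layer),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(fw$aux_logits[[k]], aux_logits(feats, b$aux_head),
                 tolerance = 1e-12)
  }
  manual <- t(vapply(seq_len(nrow(fw$p)), function(i) {
    ms <- lapply(fw$masses, function(m) simple_mass(f, m[i, 1:2], m[i, 3]))
    unname(pignistic(fuse_evidence(ms)))
  }, numeric(2)))
  expect_equal(unname(fw$p), manual, tolerance = 1e-10)
  expect_equal(rowSums(fw$fused_mass), rep(1, nrow(fw$p)), tolerance = 1e-9)
  expect_equal(fw$uncertainty, unname(fw$fused_mass[, 3]))
  # missing modality input fails fast
  expect_error(model_forward(tm$model, tm$inputs["structured"]),
               "missing input")
})

test_that("baseline fusion strategies honor their contracts", {
  set.seed(6)
  n <- 5
  inputs <- list(a = matrix(rnorm(n * 4), n, 4), b = matrix(rnorm(n * 4), n, 4))
  f <- binary_frame()
  concat <- build_fusion_model(inputs, f, fusion_spec("concatenation"), seed = 2)
  expect_equal(nrow(concat$fusion_params$W1),
               sum(vapply(concat$bundles, function(b) b$encoder$cfg$output_dim, 1L)))
  fw <- model_forward(concat, inputs)
  expect_equal(dim(fw$logits), c(n, 2L))
  expect_equal(rowSums(fw$p), rep(1, n))
  feats <- lapply(seq_along(inputs), function(k)
    encode_structured(inputs[[k]], concat$bundles[[k]]$encoder))
  names(feats) <- names(inputs)
  expect_equal(baseline_fusion(feats, concat), fw$logits, tolerance = 1e-12)

  mean_m <- build_fusion_model(inputs, f, fusion_spec("mean"), seed = 2)
  att_m <- build_fusion_model(inputs, f, fusion_spec("attention"), seed = 2)
  # share projections, zero the attention scorers: attention reduces to mean
  att_m$fusion_params$P1 <- mean_m$fusion_params$P1
  att_m$fusion_params$P2 <- mean_m$fusion_params$P2
  att_m$fusion_params$pb1 <- mean_m$fusion_params$pb1
  att_m$fusion_params$pb2 <- mean_m$fusion_params$pb2
  att_m$fusion_params$W <- mean_m$fusion_params$W
  att_m$fusion_params$b <- mean_m$fusion_params$b
  att_m$fusion_params$a1 <- att_m$fusion_params$a1 * 0
  att_m$fusion_params$a2 <- att_m$fusion_params$a2 * 0
  mf <- lapply(seq_along(inputs), function(k)
    encode_structured(inputs[[k]], mean_m$bundles[[k]]$encoder))
  expect_equal(baseline_fusion(mf, att_m), baseline_fusion(mf, mean_m),
               tolerance = 1e-12)
  # identical features through identical projections equal the single path
  mean1 <- mean_m
  mean1$fusion_params$P2 <- mean1$fusion_params$P1
  mean1$fusion_params$pb2 <- mean1$fusion_params$pb1
  same <- list(mf[[1]], mf[[1]])
  addb <- function(X, W, b) sweep(X %*% W, 2, as.vector(b), "+")
  single <- addb(addb(mf[[1]], mean1$fusion_params$P1, mean1$fusion_params$pb1),
                 mean1$fusion_params$W, mean1$fusion_params$b)
  expect_equal(baseline_fusion(same, mean1), single, tolerance = 1e-12)
  expect_error(baseline_fusion(list(mf[[1]][, 1:2], mf[[2]]), concat), "width")
})

test_that("partition settings split columns disjointly and exhaustively", {
  cohort <- tiny_cohort(n = 30, seed = 2)
  mods <- split_by_partition(cohort, "modalities")
  expect_length(mods, 2L)
  expect_identical(mods$structured$columns, colnames(cohort$structured))
  types <- split_by_partition(cohort, "data_types")
  expect_length(types, 3L)
  srcs <- split_by_partition(cohort, "data_sources")
  expect_length(srcs, 8L)   # 4 structured sources + 4 note types
  for (parts in list(mods, types, srcs)) {
    cols <- unname(unlist(lapply(parts, `[[`, "columns")))
    expect_identical(sort(cols), sort(colnames(cohort$structured)))
    expect_equal(anyDuplicated(cols), 0L)
  }
  bad <- cohort
  bad$structured$mystery <- 1
  expect_error(split_by_partition(bad, "modalities"), "untagged")
})

test_that("prepared bundle inputs match the partition layout", {
  cohort <- tiny_cohort(n = 40, seed = 4)
  inputs <- prepare_bundle_inputs(cohort, "data_types", train_idx = 1:30,
                                  text_dim = 32)
  expect_identical(names(inputs), c("numerical", "categorical", "notes"))
  expect_identical(attr(inputs, "kinds"), c("structured", "structured", "notes"))
  expect_equal(ncol(inputs$notes), 32L)
  expect_true(all(vapply(inputs, nrow, 1L) == 40L))
})

test_that("predictions expose probability, evidence and uncertainty", {
  tm <- tiny_model(seed = 8)
  preds <- predict(tm$model, tm$inputs, ids = sprintf("P%02d", 1:12))
  expect_identical(names(preds), c("id", "p_positive", "m_pos", "m_neg",
                                   "m_omega", "predicted_label"))
  expect_true(all(preds$p_positive >= 0 & preds$p_positive <= 1))
  expect_equal(preds$m_pos + preds$m_neg + preds$m_omega, rep(1, 12),
               tolerance = 1e-9)
  expect_identical(preds$predicted_label, as.integer(preds$p_positive >= 0.5))
})
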