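# Shared fixtures: random restricted masses, a small multimodal cohort and a
# miniature fusion model, all generated in code under fixed seeds.

binary_frame <- function() ds_frame(c("negative", "positive"))

# Dirichlet-style random restricted mass
rand_simple_mass <- function(frame, concentration = 1) {
  x <- stats::rgamma(frame$M + 1L, concentration)
  x <- x / sum(x)
  simple_mass(frame, x[seq_len(frame$M)], x[frame$M + 1L])
}

# random general mass with arbitrary focal sets
rand_general_mass <- function(frame, n_focal = 3L) {
  sets <- list()
  while (length(sets) < n_focal) {
    s <- which(stats::runif(frame$M) > 0.5)
    if (length(s)) sets <- unique(c(sets, list(s)))
  }
  w <- stats::rgamma(length(sets), 1)
  general_mass(frame, sets, w / sum(w))
}

# small cohort with the default multimodal structure but tiny dimensions
tiny_cohort <- function(n = 200L, seed = 1L, ...) {
  generate_cohort(cohort_spec(
    n_patients = n, n_numeric = 6L, n_binary = 4L,
    n_informative_numeric = 3L, n_informative_binary = 2L,
    vocab_size = 40L, n_informative_tokens = 6L, note_length = 10L,
    seed = seed, ...))
}

# miniature trained-size model over random matrices (not trained)
tiny_model <- function(n = 12L, seed = 1L, strategy = "evidential",
                       kinds = c("structured", "notes")) {
  set.seed(seed)
  inputs <- list(structured = matrix(stats::rnorm(n * 5L), n, 5L),
                 notes = matrix(stats::rnorm(n * 7L), n, 7L))
  model <- build_fusion_model(inputs, binary_frame(), fusion_spec(strategy),
                              kinds = kinds, n_prototypes = 3L, seed = seed)
  list(model = model, inputs = inputs)
}

expect_valid_mass_row <- function(row, tol = 1e-9) {
  expect_true(all(row >= -tol))
  expect_equal(sum(row), 1, tolerance = tol)
}
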