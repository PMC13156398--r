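# Evidence mapping: the prototype-based evidential layer that turns a deep
# feature vector into a restricted mass function.  Each learned prototype acts
# as one piece of evidence whose weight decays with squared Euclidean distance
# from the input; the per-prototype masses are pooled with Dempster's rule.

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
inv_softplus <- function(y) {
  stopifnot(all(y > 0))
  y + log1p(-exp(-y))
}
logistic <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1L, max))
  e / rowSums(e)
}

#' Evidence-mapping layer configuration
#'
#' @param n_prototypes Number of prototypes H (default 20).
#' @param init_scheme Prototype placement: `"kmeans"` centroids of a feature
#'   sample (default) or `"random_sample"` (random training feature vectors).
#' @param feature_dim Dimension of the encoder feature space the layer lives in.
#' @return An object of class `em_config`.
#' @export
em_config <- function(n_prototypes = 20L, init_scheme = c("kmeans", "random_sample"),
                      feature_dim = NULL) {
  stopifnot(n_prototypes >= 1L)
  structure(list(n_prototypes = as.integer(n_prototypes),
                 init_scheme = match.arg(init_scheme),
                 feature_dim = feature_dim),
            class = "em_config")
}

#' Prototype bank of an evidential layer
#'
#' Holds the layer's learnable state in unconstrained form: prototype
#' locations, raw scale parameters (softplus-mapped to gamma > 0), raw evidence
#' strengths (logistic-mapped to beta in \[0,1\]) and raw class memberships
#' (row-softmax-mapped onto the simplex).
#'
#' @param prototypes H x d matrix of prototype locations.
#' @param raw_gamma,raw_beta Length-H unconstrained parameter vectors.
#' @param raw_membership H x M unconstrained membership matrix.
#' @param frame The [ds_frame()] of the classification task.
#' @return An object of class `prototype_bank`.
#' @export
prototype_bank <- function(prototypes, raw_gamma, raw_beta, raw_membership, frame) {
  prototypes <- as.matrix(prototypes)
  H <- nrow(prototypes)
  stopifnot(H >= 1L, length(raw_gamma) == H, length(raw_beta) == H,
            nrow(raw_membership) == H, ncol(raw_membership) == frame$M)
  structure(list(prototypes = prototypes,
                 raw_gamma = matrix(as.numeric(raw_gamma)),
                 raw_beta = matrix(as.numeric(raw_beta)),
                 raw_membership = as.matrix(raw_membership),
                 frame = frame),
            class = "prototype_bank")
}

#' @rdname prototype_bank
#' @param bank A `prototype_bank`.
#' @export
bank_gamma <- function(bank) as.vector(softplus(bank$raw_gamma))

#' @rdname prototype_bank
#' @export
bank_beta <- function(bank) as.vector(logistic(bank$raw_beta))

#' @rdname prototype_bank
#' @export
bank_membership <- function(bank) softmax_rows(bank$raw_membership)

#' Prototype activations
#'
#' The evidence strength of prototype h for input x is
#' s_h = beta_h * exp(-gamma_h * ||x - pi_h||^2), in \[0, beta_h\].
#'
#' @param x Feature vector, or an N x d matrix of feature rows.
#' @param bank A [prototype_bank()].
#' @return An N x H matrix of activations (N = 1 for a vector input).
#' @export
enn_activation <- function(x, bank) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  if (ncol(X) != ncol(bank$prototypes))
    stop("input dimension does not match prototype dimension")
  D2 <- outer(rowSums(X^2), rowSums(bank$prototypes^2), "+") -
    2 * tcrossprod(X, bank$prototypes)
  D2 <- pmax(D2, 0)
  sweep(exp(sweep(D2, 2L, -bank_gamma(bank), "*")), 2L, bank_beta(bank), "*")
}

#' Mass function contributed by one prototype
#'
#' m({c}) = u_c * s and m(Omega) = 1 - s: the prototype's class membership
#' scaled by its activation, with the remainder assigned to ignorance.
#'
#' @param s Activation in \[0, 1\].
#' @param u Membership probability vector of length M.
#' @param frame The [ds_frame()].
#' @return A [simple_mass()].
#' @export
prototype_mass <- function(s, u, frame) simple_mass(frame, u * s, 1 - s)

#' Evidential layer forward pass
#'
#' Maps a feature vector to a restricted mass function as the orthogonal sum
#' (Dempster combination) of the H per-prototype masses.  This is the eager
#' reference path built on [combine_masses()]; the training graph evaluates the
#' algebraically identical product form.
#'
#' @param x Feature vector, or an N x d matrix (row-wise application).
#' @param bank A [prototype_bank()].
#' @return A [simple_mass()] for a vector input; an N x (M+1) matrix of
#'   \[singleton masses, ignorance\] rows for a matrix input.
#' @export
enn_forward <- function(x, bank) {
  if (is.matrix(x)) {
    rows <- lapply(seq_len(nrow(x)), function(i) {
      m <- enn_forward(x[i, ], bank)
      c(m$singletons, m$ignorance)
    })
    out <- do.call(rbind, rows)
    colnames(out) <- c(bank$frame$labels, "Omega")
    return(out)
  }
  s <- as.vector(enn_activation(x, bank))
  U <- bank_membership(bank)
  masses <- lapply(seq_along(s), function(h)
    prototype_mass(s[h], U[h, ], bank$frame))
  fuse_masses(masses)
}

#' Initialize a prototype bank from sample features
#'
#' Prototypes are placed at k-means centroids of the supplied feature sample
#' (or at randomly drawn sample rows); gamma starts at the inverse mean squared
#' distance from the sample features to their nearest prototype, which keeps
#' initial activations in a responsive range even in high-dimensional feature
#' spaces where within-cluster spread dwarfs the between-centroid spread; beta
#' starts at 0.5, and memberships start near-uniform with small seeded noise.
#'
#' @param features N x d matrix of encoder outputs (N >= n_prototypes).
#' @param frame The [ds_frame()].
#' @param cfg An [em_config()].
#' @param seed Integer seed controlling centroid/sample draws and noise.
#' @return A [prototype_bank()].
#' @export
init_prototype_bank <- function(features, frame, cfg = em_config(), seed = 1L) {
  features <- as.matrix(features)
  H <- cfg$n_prototypes
  if (nrow(features) < H)
    stop("need at least as many feature rows as prototypes")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  centers <- if (cfg$init_scheme == "kmeans") {
    if (H == 1L) matrix(colMeans(features), 1L)
    else stats::kmeans(features, centers = H, nstart = 3L, iter.max = 50L)$centers
  } else {
    features[sample.int(nrow(features), H), , drop = FALSE]
  }
  centers <- unname(as.matrix(centers))
  D2 <- outer(rowSums(features^2), rowSums(centers^2), "+") -
    2 * tcrossprod(features, centers)
  msq <- mean(apply(pmax(D2, 0), 1L, min))
  if (!is.finite(msq) || msq <= 0) msq <- 1
  prototype_bank(centers,
                 raw_gamma = rep(inv_softplus(1 / msq), H),
                 raw_beta = rep(0, H),  # logistic(0) = 0.5
                 raw_membership = matrix(stats::rnorm(H * frame$M, sd = 0.01),
                                         H, frame$M),
                 frame)
}
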