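# Minimal reverse-mode automatic differentiation on dense matrices.
#
# The evidential fusion model trains by gradient descent, and its per-batch
# computation graph is small (a few hundred nodes), so a lightweight tape is
# sufficient: every operation records its parent node ids together with a
# vector-Jacobian product closure, and ad_backward() walks the tape once in
# reverse.  Values are plain base-R matrices; node handles are integers.
# Gradients are validated against central finite differences in the test suite.

tape_new <- function() {
  t <- new.env(parent = emptyenv())
  t$val <- vector("list", 256L)
  t$op <- vector("list", 256L)
  t$n <- 0L
  t
}

tp_push <- function(tape, value, parents = NULL, vjp = NULL) {
  force(value); force(parents)
  i <- tape$n + 1L
  if (i > length(tape$val)) {
    length(tape$val) <- 2L * length(tape$val)
    length(tape$op) <- 2L * length(tape$op)
  }
  tape$val[[i]] <- value
  if (!is.null(parents)) tape$op[[i]] <- list(p = parents, vjp = vjp)
  tape$n <- i
  i
}

ad_value <- function(tape, i) {
  force(i)
  tape$val[[i]]
}

# leaf node (input or parameter); x coerced to matrix
ad_input <- function(tape, x) tp_push(tape, as.matrix(x))

ad_mm <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$val[[a]]; B <- tape$val[[b]]
  tp_push(tape, A %*% B, c(a, b),
          function(g) list(tcrossprod(g, B), crossprod(A, g)))
}

# A (n x k) plus a bias stored as a 1 x k matrix, broadcast over rows
ad_add_bias <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$val[[a]]; bb <- tape$val[[b]]
  tp_push(tape, sweep(A, 2L, as.vector(bb), "+"), c(a, b),
          function(g) list(g, matrix(colSums(g), 1L)))
}

ad_add <- function(tape, a, b) {
  force(a); force(b)
  tp_push(tape, tape$val[[a]] + tape$val[[b]], c(a, b),
          function(g) list(g, g))
}

ad_sub <- function(tape, a, b) {
  force(a); force(b)
  tp_push(tape, tape$val[[a]] - tape$val[[b]], c(a, b),
          function(g) list(g, -g))
}

ad_mul <- function(tape, a, b) {
  force(a); force(b)
  A <- tape$val[[a]]; B <- tape$val[[b]]
  tp_push(tape, A * B, c(a, b), function(g) list(g * B, g * A))
}

# constant k minus node
ad_csub <- function(tape, k, a) {
  force(a)
  tp_push(tape, k - tape$val[[a]], a, function(g) list(-g))
}

# node times scalar constant
ad_smul <- function(tape, a, k) {
  force(a)
  tp_push(tape, tape$val[[a]] * k, a, function(g) list(g * k))
}

# node times constant matrix (elementwise), e.g. dropout masks, label weights
ad_mul_const <- function(tape, a, C) {
  force(a)
  tp_push(tape, tape$val[[a]] * C, a, function(g) list(g * C))
}

ad_relu <- function(tape, a) {
  force(a)
  A <- tape$val[[a]]
  tp_push(tape, pmax(A, 0), a, function(g) list(g * (A > 0)))
}

ad_exp <- function(tape, a) {
  force(a)
  E <- exp(tape$val[[a]])
  tp_push(tape, E, a, function(g) list(g * E))
}

ad_log <- function(tape, a) {
  force(a)
  A <- tape$val[[a]]
  tp_push(tape, log(A), a, function(g) list(g / A))
}

ad_sigmoid <- function(tape, a) {
  force(a)
  S <- 1 / (1 + exp(-tape$val[[a]]))
  tp_push(tape, S, a, function(g) list(g * S * (1 - S)))
}

ad_softplus <- function(tape, a) {
  force(a)
  A <- tape$val[[a]]
  V <- ifelse(A > 30, A, log1p(exp(pmin(A, 30))))
  tp_push(tape, V, a, function(g) list(g / (1 + exp(-A))))
}

ad_rowsum <- function(tape, a) {
  force(a)
  A <- tape$val[[a]]; k <- ncol(A)
  tp_push(tape, matrix(rowSums(A)), a,
          function(g) list(tcrossprod(g[, 1L], rep(1, k))))
}

ad_sum <- function(tape, a) {
  force(a)
  A <- tape$val[[a]]
  tp_push(tape, matrix(sum(A)), a,
          function(g) list(matrix(g[1L], nrow(A), ncol(A))))
}

ad_cols <- function(tape, a, idx) {
  force(a)
  A <- tape$val[[a]]
  tp_push(tape, A[, idx, drop = FALSE], a, function(g) {
    Z <- matrix(0, nrow(A), ncol(A))
    Z[, idx] <- g
    list(Z)
  })
}

ad_cbind <- function(tape, ids) {
  ids <- vapply(ids, identity, 0L)
  vals <- lapply(ids, function(i) tape$val[[i]])
  widths <- vapply(vals, ncol, 1L)
  tp_push(tape, do.call(cbind, vals), ids, function(g) {
    off <- 0L
    lapply(widths, function(w) {
      block <- g[, (off + 1L):(off + w), drop = FALSE]
      off <<- off + w
      block
    })
  })
}

# scale each row of A (n x k) by the matching entry of s (n x 1)
ad_scale_rows <- function(tape, a, s) {
  force(a); force(s)
  A <- tape$val[[a]]; S <- as.vector(tape$val[[s]])
  tp_push(tape, A * S, c(a, s), function(g)
    list(g * S, matrix(rowSums(g * A))))
}

# scale each column of A (n x k) by the matching entry of v (k x 1)
ad_colscale <- function(tape, a, v) {
  force(a); force(v)
  A <- tape$val[[a]]; V <- as.vector(tape$val[[v]])
  tp_push(tape, sweep(A, 2L, V, "*"), c(a, v), function(g)
    list(sweep(g, 2L, V, "*"), matrix(colSums(g * A))))
}

ad_clamp_min <- function(tape, a, k) {
  force(a)
  A <- tape$val[[a]]
  tp_push(tape, pmax(A, k), a, function(g) list(g * (A > k)))
}

ad_recip <- function(tape, a) {
  force(a)
  A <- tape$val[[a]]
  tp_push(tape, 1 / A, a, function(g) list(-g / A^2))
}

ad_softmax_rows <- function(tape, a) {
  force(a)
  A <- tape$val[[a]]
  E <- exp(A - apply(A, 1L, max))
  S <- E / rowSums(E)
  tp_push(tape, S, a, function(g) list(S * (g - rowSums(g * S))))
}

ad_log_softmax <- function(tape, a) {
  force(a)
  A <- tape$val[[a]]
  mx <- apply(A, 1L, max)
  LS <- sweep(A, 1L, mx + log(rowSums(exp(A - mx))), "-")
  tp_push(tape, LS, a, function(g) list(g - exp(LS) * rowSums(g)))
}

# pairwise squared Euclidean distances between rows of X (n x d) and rows of
# P (h x d); result n x h
ad_sqdist <- function(tape, x, p) {
  force(x); force(p)
  X <- tape$val[[x]]; P <- tape$val[[p]]
  D <- outer(rowSums(X^2), rowSums(P^2), "+") - 2 * tcrossprod(X, P)
  D <- pmax(D, 0)
  tp_push(tape, D, c(x, p), function(g) list(
    2 * (X * rowSums(g) - g %*% P),
    2 * (P * colSums(g) - crossprod(g, X))
  ))
}

# accumulate gradients for every node reachable from `root` (a 1 x 1 scalar)
ad_backward <- function(tape, root) {
  grads <- vector("list", tape$n)
  grads[[root]] <- matrix(1)
  for (i in root:1L) {
    g <- grads[[i]]
    op <- tape$op[[i]]
    if (is.null(g) || is.null(op)) next
    pg <- op$vjp(g)
    for (j in seq_along(op$p)) {
      pid <- op$p[[j]]
      grads[[pid]] <- if (is.null(grads[[pid]])) pg[[j]] else grads[[pid]] + pg[[j]]
    }
  }
  grads
}
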