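# Dempster-Shafer mass-function algebra: frames, general (power-set) and
# restricted (singletons + ignorance) mass functions, Dempster's combination
# rule, degree of conflict, and the pignistic transformation.

#' Frame of discernment
#'
#' A frame of discernment is the finite, ordered set of mutually exclusive
#' hypotheses over which evidence is expressed; for binary clinical outcome
#' prediction it holds the two outcome classes.
#'
#' @param labels Character vector of at least two distinct class labels.
#' @return An object of class `ds_frame`.
#' @export
#' @examples
#' ds_frame(c("survived", "died"))
ds_frame <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2L) stop("a frame needs at least two hypotheses")
  if (anyDuplicated(labels)) stop("frame labels must be distinct")
  structure(list(labels = labels, M = length(labels)), class = "ds_frame")
}

#' @export
print.ds_frame <- function(x, ...) {
  cat("Frame of discernment {", paste(x$labels, collapse = ", "), "}\n")
  invisible(x)
}

frames_equal <- function(f1, f2) identical(f1$labels, f2$labels)

stop_if_frame_mismatch <- function(m1, m2) {
  if (!frames_equal(m1$frame, m2$frame))
    stop("mass functions are defined on different frames")
}

# tolerance below which a Dempster denominator counts as total conflict
EPS_CONFLICT <- 1e-12
MASS_TOL <- 1e-9

#' General (power-set) mass function
#'
#' Assigns belief mass to arbitrary non-empty subsets of a frame.  Subsets are
#' canonicalised as sorted index vectors; zero-mass entries are dropped, so two
#' equal mass functions have identical representations.  The empty set is not
#' representable, and masses must be non-negative and sum to one.
#'
#' @param frame A [ds_frame()].
#' @param focal_sets List of integer vectors (indices into the frame labels).
#' @param masses Numeric vector of masses, one per focal set.
#' @return An object of class `general_mass`.
#' @export
#' @examples
#' f <- ds_frame(c("a", "b"))
#' general_mass(f, list(1L, 1:2), c(0.6, 0.4))
general_mass <- function(frame, focal_sets, masses) {
  stopifnot(inherits(frame, "ds_frame"), length(focal_sets) == length(masses))
  keys <- character(0)
  acc <- numeric(0)
  for (i in seq_along(focal_sets)) {
    s <- sort(unique(as.integer(focal_sets[[i]])))
    if (length(s) == 0L) stop("the empty set cannot be a focal set")
    if (any(s < 1L) || any(s > frame$M)) stop("focal set index out of range")
    if (masses[i] < -MASS_TOL) stop("masses must be non-negative")
    k <- paste(s, collapse = ",")
    j <- match(k, keys)
    if (is.na(j)) {
      keys <- c(keys, k)
      acc <- c(acc, masses[i])
    } else acc[j] <- acc[j] + masses[i]
  }
  keep <- acc > 0
  keys <- keys[keep]; acc <- acc[keep]
  if (abs(sum(acc) - 1) > MASS_TOL) stop("masses must sum to 1")
  ord <- order(keys)
  structure(list(frame = frame, keys = keys[ord], masses = acc[ord]),
            class = "general_mass")
}

gm_sets <- function(m) lapply(strsplit(m$keys, ","), as.integer)

#' Restricted mass function (singletons plus ignorance)
#'
#' The (M+1)-dimensional mass representation used by the evidential network:
#' one mass per singleton class plus the mass assigned to the whole frame
#' (the ignorance, i.e. prediction uncertainty).
#'
#' @param frame A [ds_frame()].
#' @param singletons Numeric vector of length M with the singleton masses.
#' @param ignorance Scalar mass on the whole frame.
#' @return An object of class `simple_mass`.
#' @export
#' @examples
#' f <- ds_frame(c("a", "b"))
#' simple_mass(f, c(0.6, 0), 0.4)
simple_mass <- function(frame, singletons, ignorance) {
  stopifnot(inherits(frame, "ds_frame"))
  singletons <- as.numeric(singletons)
  if (length(singletons) != frame$M)
    stop("need one singleton mass per frame label")
  if (any(singletons < -MASS_TOL) || ignorance < -MASS_TOL)
    stop("masses must be non-negative")
  if (abs(sum(singletons) + ignorance - 1) > MASS_TOL)
    stop("masses must sum to 1")
  structure(list(frame = frame,
                 singletons = pmax(singletons, 0),
                 ignorance = max(ignorance, 0)),
            class = "simple_mass")
}

#' @export
print.simple_mass <- function(x, ...) {
  cat("Restricted mass function on {",
      paste(x$frame$labels, collapse = ", "), "}\n")
  print(c(stats::setNames(x$singletons, x$frame$labels), Omega = x$ignorance))
  invisible(x)
}

#' Vacuous and Bayesian mass constructors
#'
#' The vacuous mass places all belief on the whole frame (total ignorance); it
#' is the neutral element of Dempster's rule.  A Bayesian mass places all
#' belief on singletons, i.e. it is an ordinary probability distribution.
#'
#' @param frame A [ds_frame()].
#' @return A [simple_mass()].
#' @export
vacuous_mass <- function(frame) simple_mass(frame, rep(0, frame$M), 1)

#' @param p Probability vector of length M (non-negative, sums to 1).
#' @rdname vacuous_mass
#' @export
bayesian_mass <- function(frame, p) {
  if (abs(sum(p) - 1) > MASS_TOL || any(p < 0))
    stop("p must be a probability vector")
  simple_mass(frame, p, 0)
}

#' Lift a restricted mass to the general power-set representation
#'
#' @param m A [simple_mass()].
#' @return The equivalent [general_mass()].
#' @export
as_general_mass <- function(m) {
  stopifnot(inherits(m, "simple_mass"))
  sets <- c(as.list(seq_len(m$frame$M)), list(seq_len(m$frame$M)))
  general_mass(m$frame, sets, c(m$singletons, m$ignorance))
}

#' Degree of conflict between two mass functions
#'
#' The total product mass assigned to pairs of contradictory (disjoint) focal
#' sets; this is the normalising quantity in Dempster's rule and measures how
#' much the two pieces of evidence disagree.
#'
#' @param m1,m2 Mass functions on the same frame (`simple_mass` or
#'   `general_mass` in any combination).
#' @return A scalar in \[0, 1\].
#' @export
conflict_degree <- function(m1, m2) {
  stop_if_frame_mismatch(m1, m2)
  if (inherits(m1, "simple_mass") && inherits(m2, "simple_mass")) {
    s1 <- m1$singletons; s2 <- m2$singletons
    return(sum(s1) * sum(s2) - sum(s1 * s2))
  }
  g1 <- if (inherits(m1, "simple_mass")) as_general_mass(m1) else m1
  g2 <- if (inherits(m2, "simple_mass")) as_general_mass(m2) else m2
  sets1 <- gm_sets(g1); sets2 <- gm_sets(g2)
  kappa <- 0
  for (i in seq_along(sets1)) for (j in seq_along(sets2)) {
    if (length(intersect(sets1[[i]], sets2[[j]])) == 0L)
      kappa <- kappa + g1$masses[i] * g2$masses[j]
  }
  kappa
}

#' Combine two mass functions with Dempster's rule
#'
#' Conjunctive, conflict-renormalised pooling of two independent items of
#' evidence.  Combining two restricted masses stays within the restricted
#' family (only singletons and the full frame can remain focal) and is computed
#' in closed form; any other combination is evaluated on the power set.
#'
#' @param m1,m2 Mass functions on the same frame.
#' @return A combined mass of the same representation as the inputs
#'   (`simple_mass` if both inputs are restricted, otherwise `general_mass`),
#'   with the degree of conflict attached as attribute `"conflict"`.
#' @export
#' @examples
#' f <- ds_frame(c("a", "b"))
#' m1 <- simple_mass(f, c(0.6, 0), 0.4)
#' m2 <- simple_mass(f, c(0, 0.5), 0.5)
#' combine_masses(m1, m2)
combine_masses <- function(m1, m2) {
  stop_if_frame_mismatch(m1, m2)
  if (inherits(m1, "simple_mass") && inherits(m2, "simple_mass"))
    return(combine_simple(m1, m2))
  g1 <- if (inherits(m1, "simple_mass")) as_general_mass(m1) else m1
  g2 <- if (inherits(m2, "simple_mass")) as_general_mass(m2) else m2
  combine_general(g1, g2)
}

combine_general <- function(m1, m2) {
  sets1 <- gm_sets(m1); sets2 <- gm_sets(m2)
  out <- new.env(parent = emptyenv())
  kappa <- 0
  for (i in seq_along(sets1)) for (j in seq_along(sets2)) {
    inter <- intersect(sets1[[i]], sets2[[j]])
    w <- m1$masses[i] * m2$masses[j]
    if (length(inter) == 0L) {
      kappa <- kappa + w
    } else {
      k <- paste(inter, collapse = ",")
      out[[k]] <- (if (is.null(out[[k]])) 0 else out[[k]]) + w
    }
  }
  if (kappa >= 1 - EPS_CONFLICT)
    stop(sprintf("total conflict between evidence (kappa = %.15f)", kappa))
  keys <- ls(out)
  masses <- unname(vapply(keys, function(k) out[[k]], 0)) / (1 - kappa)
  res <- general_mass(m1$frame, lapply(strsplit(keys, ","), as.integer), masses)
  attr(res, "conflict") <- kappa
  res
}

# closed-form Dempster combination of two restricted masses; smooth in both
# inputs (used elementwise by the differentiable training graph)
combine_simple <- function(m1, m2) {
  s1 <- m1$singletons; w1 <- m1$ignorance
  s2 <- m2$singletons; w2 <- m2$ignorance
  kappa <- sum(s1) * sum(s2) - sum(s1 * s2)
  if (kappa >= 1 - EPS_CONFLICT)
    stop(sprintf("total conflict between evidence (kappa = %.15f)", kappa))
  num_s <- s1 * s2 + s1 * w2 + w1 * s2
  num_w <- w1 * w2
  z <- 1 - kappa
  res <- simple_mass(m1$frame, num_s / z, num_w / z)
  attr(res, "conflict") <- kappa
  res
}

#' Fuse a list of mass functions with Dempster's rule
#'
#' Left fold of pairwise combination; associativity of Dempster's rule makes
#' the order irrelevant up to floating-point noise.
#'
#' @param masses Non-empty list of mass functions on a shared frame.
#' @return The combined mass (a single input is returned unchanged).
#' @export
fuse_masses <- function(masses) {
  stopifnot(is.list(masses), length(masses) >= 1L)
  Reduce(combine_masses, masses)
}

#' Pignistic transformation
#'
#' Converts a mass function into a probability distribution by splitting each
#' focal set's mass equally among its elements; for a restricted mass this is
#' p(c) = m({c}) + m(Omega)/M.
#'
#' @param m A `simple_mass` or `general_mass`.
#' @return Named probability vector over the frame labels.
#' @export
#' @examples
#' f <- ds_frame(c("a", "b"))
#' pignistic(simple_mass(f, c(0.5, 0.2), 0.3))
pignistic <- function(m) UseMethod("pignistic")

#' @export
pignistic.simple_mass <- function(m) {
  p <- m$singletons + m$ignorance / m$frame$M
  stats::setNames(p, m$frame$labels)
}

#' @export
pignistic.general_mass <- function(m) {
  p <- numeric(m$frame$M)
  sets <- gm_sets(m)
  for (i in seq_along(sets))
    p[sets[[i]]] <- p[sets[[i]]] + m$masses[i] / length(sets[[i]])
  stats::setNames(p, m$frame$labels)
}

#' Serialize a mass function to JSON
#'
#' Restricted masses serialize as `{"labels": [...], "singletons": [...],
#' "ignorance": x}`; general masses as a list of `[indices, mass]` focal-set
#' pairs alongside the labels.
#'
#' @param m A mass function.
#' @return A JSON string.
#' @export
mass_to_json <- function(m) {
  if (inherits(m, "simple_mass")) {
    jsonlite::toJSON(list(labels = m$frame$labels,
                          singletons = m$singletons,
                          ignorance = m$ignorance),
                     auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::toJSON(list(labels = m$frame$labels,
                          focal_sets = unname(Map(function(s, w)
                            list(indices = s, mass = w), gm_sets(m),
                            as.list(m$masses)))),
                     auto_unbox = TRUE, digits = NA)
  }
}

#' Deserialize a mass function from JSON
#'
#' @param json A JSON string produced by [mass_to_json()].
#' @return A `simple_mass` or `general_mass`.
#' @export
mass_from_json <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  frame <- ds_frame(unlist(x$labels))
  if (!is.null(x$singletons)) {
    simple_mass(frame, unlist(x$singletons), x$ignorance)
  } else {
    general_mass(frame,
                 lapply(x$focal_sets, function(fs) unlist(fs$indices)),
                 vapply(x$focal_sets, function(fs) fs$mass, 0))
  }
}
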