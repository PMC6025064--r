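## Capacity (fuzzy measure) algebra over subsets of a finite attribute set.
## Subsets are encoded as bitmasks over the attribute order: attribute i
## (1-based) corresponds to bit 2^(i-1). A set function on n attributes is a
## numeric vector of length 2^n indexed by mask + 1 (index 1 = empty set).

#' Subset label for a bitmask
#'
#' Canonical human-readable label for a subset: member attribute names in
#' input order joined with "+"; the empty set is "{}".
#'
#' @param mask Integer bitmask.
#' @param attributes Character vector of attribute names.
#' @return A single string.
#' @keywords internal
subset_label <- function(mask, attributes) {
  if (mask == 0L) return("{}")
  paste(attributes[bit_members(mask)], collapse = "+")
}

## indices of the attributes present in a bitmask
bit_members <- function(mask) {
  which(bitwAnd(mask, bitwShiftL(1L, seq_len(31L) - 1L)) != 0L)
}

bit_size <- function(mask) length(bit_members(mask))

## sizes of all masks 0..2^n-1, vectorized
all_mask_sizes <- function(n) {
  sizes <- integer(2^n)
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    sizes <- sizes + as.integer(bitwAnd(0:(2^n - 1L), bit) != 0L)
  }
  sizes
}

#' Construct a capacity (fuzzy measure)
#'
#' A capacity is a normalized monotone set function v on the attribute set:
#' v(empty) = 0, v(full set) = 1, and v(S) <= v(T) whenever S is a subset of
#' T. It generalizes additive attribute weights; the Choquet integral
#' aggregates attribute values with respect to it.
#'
#' @param values Numeric vector of length 2^n giving v for every subset in
#'   bitmask order (empty set first), or a named vector keyed by subset
#'   labels (attribute names joined with "+", "{}" for the empty set).
#' @param attributes Character vector of n >= 2 attribute names.
#' @param validate If TRUE (default), reject non-normalized or non-monotone
#'   input. With FALSE an invalid set function can be built for inspection
#'   with [check_monotone()].
#' @param tol Monotonicity tolerance used during validation.
#' @return An object of class `capacity`.
#' @examples
#' v <- capacity(c(0, .5, .5, 1), c("sweet", "sour"))
#' shapley(v)
#' @seealso [to_mobius()], [choquet()], [shapley()], [interaction_matrix()]
#' @export
capacity <- function(values, attributes, validate = TRUE, tol = 1e-9) {
  n <- length(attributes)
  if (n < 2) stop("need at least 2 attributes")
  if (anyDuplicated(attributes)) stop("duplicate attribute names")
  N <- 2^n
  if (!is.null(names(values))) {
    labs <- vapply(0:(N - 1L), subset_label, "", attributes = attributes)
    if (!setequal(names(values), labs))
      stop("named values must cover every subset exactly once")
    values <- unname(values[labs])
  }
  if (length(values) != N)
    stop(sprintf("expected %d subset values, got %d", N, length(values)))
  v <- structure(list(attributes = attributes, values = as.numeric(values)),
                 class = "capacity")
  if (validate) {
    if (abs(v$values[1]) > tol)
      stop("capacity not normalized: v(empty set) must be 0")
    if (abs(v$values[N] - 1) > tol)
      stop("capacity not normalized: v(full set) must be 1")
    viol <- check_monotone(v, tol = tol)
    if (nrow(viol) > 0)
      stop(sprintf("capacity not monotone: v(%s)=%.6g > v(%s)=%.6g",
                   viol$subset[1], viol$value_subset[1],
                   viol$superset[1], viol$value_superset[1]))
  }
  v
}

#' @export
print.capacity <- function(x, ...) {
  n <- length(x$attributes)
  cat(sprintf("Capacity on %d attributes: %s\n", n,
              paste(x$attributes, collapse = ", ")))
  labs <- vapply(0:(2^n - 1L), subset_label, "", attributes = x$attributes)
  print(stats::setNames(round(x$values, 4), labs))
  invisible(x)
}

#' Check monotonicity of a set function
#'
#' Reports every covering pair S < T = S + {i} with v(S) > v(T) + tol.
#' Covering pairs suffice: monotonicity over them implies it for all nested
#' pairs by transitivity.
#'
#' @param capacity A `capacity` (possibly built with `validate = FALSE`).
#' @param tol Nonnegative tolerance.
#' @return A data frame with columns `subset`, `superset`, `value_subset`,
#'   `value_superset`; zero rows when the set function is monotone.
#' @export
check_monotone <- function(capacity, tol = 1e-9) {
  stopifnot(inherits(capacity, "capacity"))
  n <- length(capacity$attributes)
  v <- capacity$values
  sub <- character(0); sup <- character(0); vs <- numeric(0); vt <- numeric(0)
  for (mask in 0:(2^n - 1L)) {
    for (i in seq_len(n)) {
      bit <- bitwShiftL(1L, i - 1L)
      if (bitwAnd(mask, bit) != 0L) next
      up <- bitwOr(mask, bit)
      if (v[mask + 1L] > v[up + 1L] + tol) {
        sub <- c(sub, subset_label(mask, capacity$attributes))
        sup <- c(sup, subset_label(up, capacity$attributes))
        vs <- c(vs, v[mask + 1L]); vt <- c(vt, v[up + 1L])
      }
    }
  }
  data.frame(subset = sub, superset = sup,
             value_subset = vs, value_superset = vt,
             stringsAsFactors = FALSE)
}

#' Möbius transform of a capacity
#'
#' Re-parameterizes a capacity by its Möbius coefficients
#' m(S) = sum over T in S of (-1)^(|S \ T|) v(T); the inverse (zeta)
#' transform recovers v(S) = sum over T in S of m(T). The coefficients of all
#' nonempty subsets sum to 1. k-additive capacities have m(S) = 0 for
#' |S| > k; an additive capacity has only singleton coefficients.
#'
#' @param capacity A valid `capacity`.
#' @return A `mobius_capacity`: attributes, coefficients over all subsets
#'   (empty set coefficient is 0), and the detected `k_additive` order (the
#'   largest subset size with a coefficient exceeding 1e-12 in magnitude).
#' @export
to_mobius <- function(capacity) {
  stopifnot(inherits(capacity, "capacity"))
  n <- length(capacity$attributes)
  m <- capacity$values
  ## fast Moebius transform: subtract subset sums one bit at a time
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    for (mask in 0:(2^n - 1L)) {
      if (bitwAnd(mask, bit) != 0L)
        m[mask + 1L] <- m[mask + 1L] - m[bitwXor(mask, bit) + 1L]
    }
  }
  sizes <- all_mask_sizes(n)
  k <- max(c(1L, sizes[abs(m) > 1e-12]))
  mobius_capacity(m, capacity$attributes, k_additive = k)
}

#' Construct a Möbius representation directly
#'
#' @param coefficients Numeric vector of length 2^n over all subsets in
#'   bitmask order (empty set first, coefficient 0), or of length 2^n - 1
#'   over nonempty subsets.
#' @param attributes Attribute names.
#' @param k_additive Largest interacting subset size, or "full".
#' @return A `mobius_capacity`.
#' @export
mobius_capacity <- function(coefficients, attributes, k_additive = "full") {
  n <- length(attributes)
  if (length(coefficients) == 2^n - 1L) coefficients <- c(0, coefficients)
  if (length(coefficients) != 2^n)
    stop(sprintf("expected %d or %d coefficients", 2^n, 2^n - 1L))
  s <- sum(coefficients[-1L])
  if (abs(s - 1) > 1e-8)
    stop(sprintf("Moebius coefficients must sum to 1 (got %.8g)", s))
  if (!identical(k_additive, "full")) {
    sizes <- all_mask_sizes(n)
    bad <- abs(coefficients) > 1e-12 & sizes > k_additive
    if (any(bad)) stop("nonzero coefficient above the stated k_additive order")
  }
  structure(list(attributes = attributes,
                 coefficients = as.numeric(coefficients),
                 k_additive = k_additive),
            class = "mobius_capacity")
}

#' @export
print.mobius_capacity <- function(x, ...) {
  n <- length(x$attributes)
  cat(sprintf("Moebius capacity on %d attributes (k_additive = %s)\n",
              n, as.character(x$k_additive)))
  labs <- vapply(0:(2^n - 1L), subset_label, "", attributes = x$attributes)
  keep <- abs(x$coefficients) > 1e-12
  print(stats::setNames(round(x$coefficients[keep], 4), labs[keep]))
  invisible(x)
}

#' Zeta transform: rebuild a capacity from Möbius coefficients
#'
#' @param mobius A `mobius_capacity`.
#' @param tol Monotonicity tolerance for validating the result.
#' @return A `capacity`; errors if the coefficients imply a non-monotone set
#'   function (the caller built an infeasible Möbius vector).
#' @export
from_mobius <- function(mobius, tol = 1e-9) {
  stopifnot(inherits(mobius, "mobius_capacity"))
  n <- length(mobius$attributes)
  v <- mobius$coefficients
  ## fast zeta transform: accumulate subset sums one bit at a time
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    for (mask in 0:(2^n - 1L)) {
      if (bitwAnd(mask, bit) != 0L)
        v[mask + 1L] <- v[mask + 1L] + v[bitwXor(mask, bit) + 1L]
    }
  }
  capacity(v, mobius$attributes, validate = TRUE, tol = tol)
}

#' Choquet integral
#'
#' Aggregates attribute values x (commensurable, each in \[0,1\]) with respect
#' to a capacity: sum over the ascending order statistics of
#' (x_(i) - x_(i-1)) v(A_(i)), where A_(i) is the set of attributes whose
#' value is at least x_(i). Reduces to the weighted arithmetic mean for an
#' additive capacity and is idempotent on constant inputs. For a Möbius
#' representation the equivalent min-form sum over subsets
#' m(S) min_{i in S} x_i is used.
#'
#' @param capacity A `capacity` or `mobius_capacity`.
#' @param x Numeric vector, one value per attribute, each in \[0,1\].
#' @return A single number in \[min(x), max(x)\].
#' @export
choquet <- function(capacity, x) UseMethod("choquet")

check_choquet_input <- function(attributes, x) {
  if (length(x) != length(attributes))
    stop(sprintf("x must have %d values (one per attribute), got %d",
                 length(attributes), length(x)))
  if (any(!is.finite(x)) || any(x < -1e-12) || any(x > 1 + 1e-12))
    stop("attribute values must lie in [0,1]; scale first (scale_minmax)")
  pmin(pmax(as.numeric(x), 0), 1)
}

#' @rdname choquet
#' @export
choquet.capacity <- function(capacity, x) {
  x <- check_choquet_input(capacity$attributes, x)
  ord <- order(x)                      # ascending
  n <- length(x)
  xs <- c(0, x[ord])
  ## A_(i): attributes with value >= x_(i) = those ranked i..n
  total <- 0
  remaining <- sum(bitwShiftL(1L, ord - 1L))
  for (i in seq_len(n)) {
    total <- total + (xs[i + 1L] - xs[i]) * capacity$values[remaining + 1L]
    remaining <- remaining - bitwShiftL(1L, ord[i] - 1L)
  }
  total
}

#' @rdname choquet
#' @export
choquet.mobius_capacity <- function(capacity, x) {
  x <- check_choquet_input(capacity$attributes, x)
  n <- length(x)
  total <- 0
  for (mask in 1:(2^n - 1L)) {
    m <- capacity$coefficients[mask + 1L]
    if (m != 0) total <- total + m * min(x[bit_members(mask)])
  }
  total
}

#' Shapley values of a capacity
#'
#' Each attribute's average marginal contribution to the capacity over all
#' attribute orderings:
#' phi_i = sum over S not containing i of
#' |S|! (n-|S|-1)! / n! * (v(S + i) - v(S)).
#' The values sum to 1 and, for a monotone capacity, lie in \[0,1\]; they are
#' the relative-importance measure reported for each attribute.
#'
#' @param capacity A `capacity` or `mobius_capacity`.
#' @return Named numeric vector of length n summing to 1.
#' @export
shapley <- function(capacity) UseMethod("shapley")

#' @rdname shapley
#' @export
shapley.capacity <- function(capacity) {
  n <- length(capacity$attributes)
  v <- capacity$values
  sizes <- all_mask_sizes(n)
  lf <- lfactorial(0:n)
  phi <- numeric(n)
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    masks <- which(bitwAnd(0:(2^n - 1L), bit) == 0L) - 1L
    s <- sizes[masks + 1L]
    w <- exp(lf[s + 1L] + lf[n - s] - lf[n + 1L])
    phi[i] <- sum(w * (v[bitwOr(masks, bit) + 1L] - v[masks + 1L]))
  }
  stats::setNames(phi, capacity$attributes)
}

#' @rdname shapley
#' @export
shapley.mobius_capacity <- function(capacity) {
  ## phi_i = sum over subsets T containing i of m(T)/|T|
  n <- length(capacity$attributes)
  m <- capacity$coefficients
  sizes <- all_mask_sizes(n)
  phi <- numeric(n)
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    has <- bitwAnd(0:(2^n - 1L), bit) != 0L
    phi[i] <- sum(m[has] / sizes[has])
  }
  stats::setNames(phi, capacity$attributes)
}

#' Pairwise Shapley interaction indices
#'
#' The Shapley interaction index of an unordered attribute pair (i, j):
#' I(i,j) = sum over S in N \ {i,j} of
#' |S|! (n-|S|-2)! / (n-1)! * (v(S+ij) - v(S+i) - v(S+j) + v(S)).
#' Positive values mean the pair is complementary (their joint presence is
#' worth more than the sum of their separate contributions), negative values
#' substitutive. For a Möbius representation the equivalent form
#' sum over T containing both of m(T)/(|T|-1) is used. An additive capacity
#' has all interactions zero. Values lie in \[-1, 1\].
#'
#' @param capacity A `capacity` or `mobius_capacity`.
#' @return Symmetric n x n matrix with zero diagonal, dimnames = attributes.
#' @export
interaction_matrix <- function(capacity) UseMethod("interaction_matrix")

#' @rdname interaction_matrix
#' @export
interaction_matrix.capacity <- function(capacity) {
  n <- length(capacity$attributes)
  v <- capacity$values
  sizes <- all_mask_sizes(n)
  lf <- lfactorial(0:n)
  I <- matrix(0, n, n, dimnames = list(capacity$attributes, capacity$attributes))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    bi <- bitwShiftL(1L, i - 1L); bj <- bitwShiftL(1L, j - 1L)
    bij <- bitwOr(bi, bj)
    masks <- which(bitwAnd(0:(2^n - 1L), bij) == 0L) - 1L
    s <- sizes[masks + 1L]
    w <- exp(lf[s + 1L] + lf[n - s - 1L] - lf[n])
    d <- v[bitwOr(masks, bij) + 1L] - v[bitwOr(masks, bi) + 1L] -
         v[bitwOr(masks, bj) + 1L] + v[masks + 1L]
    I[i, j] <- I[j, i] <- sum(w * d)
  }
  I
}

#' @rdname interaction_matrix
#' @export
interaction_matrix.mobius_capacity <- function(capacity) {
  n <- length(capacity$attributes)
  m <- capacity$coefficients
  sizes <- all_mask_sizes(n)
  I <- matrix(0, n, n, dimnames = list(capacity$attributes, capacity$attributes))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    bij <- bitwOr(bitwShiftL(1L, i - 1L), bitwShiftL(1L, j - 1L))
    has <- bitwAnd(0:(2^n - 1L), bij) == bij
    I[i, j] <- I[j, i] <- sum(m[has] / (sizes[has] - 1L))
  }
  I
}
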