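## Penalized B-spline smoothing of time series into differentiable functional
## curves. Basis evaluation and derivatives go through splines::splineDesign;
## the roughness penalty integrates the squared second derivative with
## composite Simpson quadrature on each knot span (the integrand is piecewise
## polynomial, so a dense Simpson rule is effectively exact at the tolerances
## used here).

#' Construct a B-spline basis
#'
#' @param t_min,t_max Domain endpoints in seconds (`t_max > t_min`).
#' @param n_basis Number of basis functions (>= order).
#' @param order Spline order = polynomial degree + 1; order 4 (cubic, the
#'   default) gives curves with continuous first and second derivatives.
#' @return A `bspline_basis`: domain, order, equally spaced interior knots
#'   (n_basis - order of them), the full replicated knot vector, and
#'   `n_basis`. Basis functions form a partition of unity on the domain.
#' @export
make_bspline_basis <- function(t_min, t_max, n_basis, order = 4) {
  if (!(t_max > t_min)) stop("t_max must exceed t_min")
  order <- as.integer(order); n_basis <- as.integer(n_basis)
  if (order < 1) stop("order must be >= 1")
  if (n_basis < order) stop("n_basis must be >= order")
  n_int <- n_basis - order
  interior <- if (n_int > 0)
    seq(t_min, t_max, length.out = n_int + 2L)[-c(1L, n_int + 2L)]
  else numeric(0)
  structure(list(domain = c(t_min, t_max), order = order,
                 interior_knots = interior,
                 knots = c(rep(t_min, order), interior, rep(t_max, order)),
                 n_basis = n_basis),
            class = "bspline_basis")
}

#' @export
print.bspline_basis <- function(x, ...) {
  cat(sprintf("B-spline basis: order %d, %d functions on [%g, %g], %d interior knots\n",
              x$order, x$n_basis, x$domain[1], x$domain[2],
              length(x$interior_knots)))
  invisible(x)
}

#' Evaluate the basis functions (or a derivative) at given times
#'
#' @param basis A `bspline_basis`.
#' @param times Evaluation points inside the domain.
#' @param deriv Derivative order (0 = function values).
#' @return Matrix, length(times) x n_basis.
#' @export
eval_basis <- function(basis, times, deriv = 0) {
  stopifnot(inherits(basis, "bspline_basis"))
  times <- as.numeric(times)
  eps <- 1e-8 * max(1, abs(basis$domain))
  if (any(times < basis$domain[1] - eps) || any(times > basis$domain[2] + eps))
    stop(sprintf("time outside basis domain [%g, %g]; no extrapolation",
                 basis$domain[1], basis$domain[2]))
  times <- pmin(pmax(times, basis$domain[1]), basis$domain[2])
  splines::splineDesign(basis$knots, times, ord = basis$order,
                        derivs = rep(as.integer(deriv), length(times)))
}

## penalty matrix R_ij = integral of B_i^(d) B_j^(d) over the domain,
## composite Simpson with npts points per knot span
penalty_matrix <- function(basis, deriv = 2, npts = 201) {
  spans <- unique(basis$knots)
  R <- matrix(0, basis$n_basis, basis$n_basis)
  if (basis$order <= deriv) return(R)  # derivative identically 0
  for (s in seq_len(length(spans) - 1L)) {
    a <- spans[s]; b <- spans[s + 1L]
    if (b <= a) next
    tt <- seq(a, b, length.out = npts)
    B <- eval_basis(basis, tt, deriv = deriv)
    w <- simpson_weights(npts) * (b - a) / (npts - 1)
    R <- R + crossprod(B * sqrt(w))
  }
  (R + t(R)) / 2
}

simpson_weights <- function(npts) {
  stopifnot(npts >= 3, npts %% 2 == 1)
  w <- rep(c(4, 2), length.out = npts - 2)
  c(1, w[-length(w)], 4, 1) / 3
}

#' Penalized B-spline smoothing of a sampled series
#'
#' Finds the basis coefficients minimizing
#' `sum_j (values_j - f(times_j))^2 + lambda * integral(f''(t)^2 dt)`.
#' With `lambda = NULL` the penalty weight is selected by generalized
#' cross-validation over a log-spaced grid from 1e-6 to 1e4. `lambda = 0`
#' with `n_basis` equal to the number of points interpolates; very large
#' lambda shrinks the fit toward the ordinary least-squares straight line
#' (the null space of the curvature penalty).
#'
#' @param times Observation times (>= 2 distinct, inside the basis domain).
#' @param values Observed values, one per time.
#' @param basis A `bspline_basis`.
#' @param lambda Nonnegative penalty weight, or NULL for GCV selection.
#' @param label Optional name for the resulting curve.
#' @return A `functional_curve`: basis, coefficients, label, the lambda used,
#'   effective degrees of freedom `df`, `residual_sse`, and `gcv`.
#' @export
smooth_penalized <- function(times, values, basis, lambda = NULL,
                             label = NULL) {
  stopifnot(inherits(basis, "bspline_basis"))
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values)) stop("times and values differ in length")
  if (any(!is.finite(values))) stop("values must be finite")
  if (length(unique(times)) < 2) stop("need at least 2 distinct times")
  B <- eval_basis(basis, times)
  R <- penalty_matrix(basis, deriv = 2)
  BtB <- crossprod(B); Bty <- crossprod(B, values)
  n <- length(values)

  solve_at <- function(lam) {
    M <- BtB + lam * R
    coefs <- tryCatch(solve(M, Bty), error = function(e)
      stop("singular penalized normal equations (too few distinct times ",
           "for the basis size, or lambda too small): ", conditionMessage(e),
           call. = FALSE))
    fitted <- as.numeric(B %*% coefs)
    sse <- sum((values - fitted)^2)
    df <- sum(diag(solve(M, BtB)))      # trace of the hat matrix
    gcv <- if (n > df) n * sse / (n - df)^2 else Inf
    list(coefs = as.numeric(coefs), sse = sse, df = df, gcv = gcv)
  }

  if (is.null(lambda)) {
    grid <- 10^seq(-6, 4, length.out = 41)
    fits <- lapply(grid, function(l) tryCatch(solve_at(l), error = function(e) NULL))
    ok <- !vapply(fits, is.null, TRUE)
    if (!any(ok)) stop("GCV search failed at every candidate lambda")
    gcvs <- vapply(fits[ok], `[[`, 0, "gcv")
    best <- which(ok)[which.min(gcvs)]
    lambda <- grid[best]
    sol <- fits[[best]]
  } else {
    if (lambda < 0) stop("lambda must be nonnegative")
    sol <- solve_at(lambda)
  }
  structure(list(basis = basis, coefficients = sol$coefs, label = label,
                 lambda = lambda, df = sol$df, residual_sse = sol$sse,
                 gcv = sol$gcv),
            class = "functional_curve")
}

#' Evaluate a functional curve or its derivatives
#'
#' Exact basis-expansion evaluation; derivatives up to order - 1 are defined
#' (order 4 gives meaningful first and second derivatives). Times outside
#' the basis domain are an error — curves are never extrapolated.
#'
#' @param curve A `functional_curve`.
#' @param times Evaluation grid inside the domain.
#' @param deriv 0 (values), 1 or 2.
#' @return Numeric vector, one value per time.
#' @export
eval_curve <- function(curve, times, deriv = 0) {
  stopifnot(inherits(curve, "functional_curve"))
  as.numeric(eval_basis(curve$basis, times, deriv = deriv) %*% curve$coefficients)
}

#' @export
print.functional_curve <- function(x, ...) {
  cat(sprintf("Functional curve%s: %d basis coefficients on [%g, %g], lambda = %g, df = %.2f\n",
              if (!is.null(x$label)) paste0(" '", x$label, "'") else "",
              x$basis$n_basis, x$basis$domain[1], x$basis$domain[2],
              x$lambda, x$df))
  invisible(x)
}

#' Serialize a functional curve to JSON text
#'
#' Full-precision ("%.17g") encoding of domain, order, knots and
#' coefficients; [curve_from_json()] restores the curve bit-exactly.
#'
#' @param curve A `functional_curve`.
#' @return A JSON string.
#' @export
curve_to_json <- function(curve) {
  stopifnot(inherits(curve, "functional_curve"))
  jsonlite::toJSON(list(
    label = curve$label,
    domain = curve$basis$domain,
    order = curve$basis$order,
    n_basis = curve$basis$n_basis,
    interior_knots = curve$basis$interior_knots,
    coefficients = curve$coefficients,
    lambda = curve$lambda), auto_unbox = TRUE, digits = I(17), null = "null")
}

#' Restore a functional curve from JSON text
#'
#' @param txt JSON produced by [curve_to_json()].
#' @return A `functional_curve`.
#' @export
curve_from_json <- function(txt) {
  o <- jsonlite::fromJSON(txt)
  basis <- make_bspline_basis(o$domain[1], o$domain[2], o$n_basis, o$order)
  ## keep the serialized knots verbatim (guards against rounding drift)
  if (length(o$interior_knots))
    basis$interior_knots <- as.numeric(o$interior_knots)
  basis$knots <- c(rep(o$domain[1], o$order), basis$interior_knots,
                   rep(o$domain[2], o$order))
  structure(list(basis = basis, coefficients = as.numeric(o$coefficients),
                 label = o$label, lambda = o$lambda, df = NA_real_,
                 residual_sse = NA_real_, gcv = NA_real_),
            class = "functional_curve")
}
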