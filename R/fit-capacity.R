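## Least-squares identification of a k-additive capacity from sample data.
## The Choquet integral is linear in the Moebius coefficients
## (C_m(x) = sum_S m(S) min_{i in S} x_i), so the fit is a quadratic program
## with one normalization equality and the monotonicity inequalities
## sum_{T subset of S} m(T + {i}) >= 0 for every attribute i and S in N\{i}.

#' Min–max scale a sample table to \[0,1\]
#'
#' Maps each variable (column) affinely so its observed minimum becomes 0 and
#' its maximum 1, recording the extrema so the map can be inverted exactly.
#' The Choquet integral requires commensurable inputs; per-fit min–max
#' scaling is the standard way to put line-scale attributes and liking on a
#' common \[0,1\] scale. A constant column carries no information for the fit:
#' it is mapped to 0.5 everywhere and flagged.
#'
#' @param table Numeric matrix or data frame, samples x variables.
#' @return List with `scaled` (matrix in \[0,1\]) and `records` (data frame
#'   with `variable`, `min`, `max`, `constant`).
#' @seealso [unscale_minmax()]
#' @export
scale_minmax <- function(table) {
  X <- as.matrix(table)
  if (nrow(X) < 1) stop("need at least one sample")
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  const <- (hi - lo) < .Machine$double.eps * pmax(1, abs(hi))
  S <- X
  for (j in seq_len(ncol(X)))
    S[, j] <- if (const[j]) rep(0.5, nrow(X)) else (X[, j] - lo[j]) / (hi[j] - lo[j])
  list(scaled = S,
       records = data.frame(variable = colnames(X), min = lo, max = hi,
                            constant = const, row.names = NULL,
                            stringsAsFactors = FALSE))
}

#' Invert a min–max scaling
#'
#' @param scaled Matrix produced by [scale_minmax()].
#' @param records The scaling records from the same call. Constant columns
#'   are restored to their recorded constant value.
#' @return Matrix on the original scale.
#' @export
unscale_minmax <- function(scaled, records) {
  X <- as.matrix(scaled)
  for (j in seq_len(ncol(X))) {
    r <- records[j, ]
    X[, j] <- if (r$constant) rep(r$min, nrow(X)) else r$min + X[, j] * (r$max - r$min)
  }
  X
}

## masks of all nonempty subsets with size <= k, in bitmask order
k_additive_masks <- function(n, k) {
  sizes <- all_mask_sizes(n)
  which(sizes >= 1L & sizes <= k) - 1L
}

## design matrix of the Moebius min-form: Z[obs, subset] = min_{i in S} x_i
mobius_design <- function(X, masks) {
  Z <- matrix(0, nrow(X), length(masks))
  for (j in seq_along(masks)) {
    idx <- bit_members(masks[j])
    Z[, j] <- if (length(idx) == 1L) X[, idx] else
      apply(X[, idx, drop = FALSE], 1, min)
  }
  Z
}

## monotonicity constraint matrix A m >= 0 on the k-additive Moebius vector:
## one row per (attribute i, subset S of N\{i}); duplicate rows removed.
monotonicity_constraints <- function(n, masks) {
  p <- length(masks)
  pos <- integer(2^n); pos[masks + 1L] <- seq_len(p)   # mask -> column
  rows <- list()
  for (i in seq_len(n)) {
    bit <- bitwShiftL(1L, i - 1L)
    others <- which(bitwAnd(0:(2^n - 1L), bit) == 0L) - 1L
    for (S in others) {
      a <- numeric(p)
      ## all T subset of S: enumerate submasks of S
      sub <- S
      repeat {
        m2 <- bitwOr(sub, bit)
        j <- if (m2 < 2^n) pos[m2 + 1L] else 0L
        if (j > 0L) a[j] <- a[j] + 1
        if (sub == 0L) break
        sub <- bitwAnd(sub - 1L, S)
      }
      rows[[length(rows) + 1L]] <- a
    }
  }
  A <- do.call(rbind, rows)
  unique(A)
}

#' Fit a k-additive capacity by constrained least squares
#'
#' Identifies the Möbius coefficients m of a k-additive capacity minimizing
#' `sum_i (Choquet_m(x_i) - y_i)^2 + ridge * ||m - m_unif||^2`
#' subject to normalization (coefficients sum to 1) and all monotonicity
#' constraints, where `m_unif` is the uniform additive capacity (weight 1/n
#' per attribute). The ridge term makes the underdetermined case (fewer
#' samples than coefficients, routine when fitting 3 products at one time
#' point) a well-posed minimum-deviation problem with a unique, deterministic
#' solution. Solved with the dual active-set method of
#' \code{quadprog::solve.QP}.
#'
#' @param X Samples x attributes matrix with values in \[0,1\]
#'   (see [scale_minmax()]).
#' @param y Response (liking) values in \[0,1\], one per sample.
#' @param k_additive Largest interacting subset size (>= 1); 2 fits direct
#'   effects plus pairwise interactions.
#' @param ridge Nonnegative ridge weight toward the uniform additive
#'   capacity; default 1e-6 perturbs determined fits negligibly while
#'   uniquely resolving underdetermined ones.
#' @param allow_underdetermined With `ridge = 0` and fewer samples than free
#'   coefficients the optimum is non-unique; this is an error unless
#'   explicitly allowed (a minimal-norm solution is then returned).
#' @return A `pointwise_fit`: `capacity` (Möbius representation), `shapley`,
#'   `interactions` (symmetric matrix, zero diagonal), `residual_sse`,
#'   `n_samples`, `n_parameters`, `underdetermined` flag, and a `scaling`
#'   slot (filled by pipeline callers, NULL here).
#' @examples
#' set.seed(1)
#' X <- matrix(runif(200), 50, 4, dimnames = list(NULL, c("a","b","c","d")))
#' y <- X %*% c(.4, .3, .2, .1)
#' fit <- fit_capacity_ls(X, y, k_additive = 2)
#' fit$shapley
#' @export
fit_capacity_ls <- function(X, y, k_additive = 2, ridge = 1e-6,
                            allow_underdetermined = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X and y must have equal sample counts")
  if (k_additive < 1) stop("k_additive must be >= 1")
  if (any(X < -1e-9) || any(X > 1 + 1e-9) || any(y < -1e-9) || any(y > 1 + 1e-9))
    stop("X and y must lie in [0,1]; scale first (scale_minmax)")
  n <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(n))
  attrs <- colnames(X)
  k <- min(k_additive, n)

  masks <- k_additive_masks(n, k)
  p <- length(masks)
  underdetermined <- nrow(X) < p
  if (underdetermined && ridge == 0 && !allow_underdetermined)
    stop(sprintf(paste0("underdetermined fit (%d samples < %d coefficients) ",
                        "with ridge = 0 has no unique optimum; set ridge > 0 ",
                        "or allow_underdetermined = TRUE"), nrow(X), p))

  Z <- mobius_design(X, masks)
  m0 <- numeric(p)
  m0[all_mask_sizes(n)[masks + 1L] == 1L] <- 1 / n   # uniform additive

  eps <- if (ridge > 0) ridge else 1e-10    # PD jitter for the ridge-free path
  Dmat <- crossprod(Z) + diag(eps, p)
  dvec <- crossprod(Z, y) + eps * m0
  Aineq <- monotonicity_constraints(n, masks)
  Amat <- cbind(rep(1, p), t(Aineq))
  bvec <- c(1, rep(0, nrow(Aineq)))

  sol <- tryCatch(
    quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = 1),
    error = function(e) stop("capacity identification QP failed: ",
                             conditionMessage(e), call. = FALSE))
  m <- sol$solution
  coefs <- numeric(2^n)
  coefs[masks + 1L] <- m
  coefs[-1L] <- coefs[-1L] / sum(coefs[-1L])   # exact renormalization
  mob <- mobius_capacity(coefs, attrs, k_additive = k)
  resid <- y - as.numeric(Z %*% m)
  structure(list(capacity = mob,
                 shapley = shapley(mob),
                 interactions = interaction_matrix(mob),
                 residual_sse = sum(resid^2),
                 n_samples = nrow(X),
                 n_parameters = p,
                 underdetermined = underdetermined,
                 ridge = ridge,
                 scaling = NULL),
            class = "pointwise_fit")
}

#' @export
print.pointwise_fit <- function(x, ...) {
  cat(sprintf("Choquet capacity fit: %d samples, %d coefficients%s\n",
              x$n_samples, x$n_parameters,
              if (x$underdetermined) " (underdetermined, ridge-regularized)" else ""))
  cat("Shapley values:\n"); print(round(x$shapley, 4))
  cat("Interaction indices:\n"); print(round(x$interactions, 4))
  cat(sprintf("Residual SSE: %.6g\n", x$residual_sse))
  invisible(x)
}
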