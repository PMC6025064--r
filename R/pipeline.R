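## Temporal-drivers-of-liking orchestration: smooth raw MATI series, evaluate
## them on a time grid, fit pointwise relative importance (Choquet/Shapley or
## LMG), smooth the importance trajectories into functional curves, and
## report the dynamics of their derivatives.

## smooth one series per (product, attribute); returns nested list
## curves[[product]][[attribute]]
smooth_mati_curves <- function(means, n_basis = NULL, order = 4,
                               lambda = NULL) {
  df <- as.data.frame(means)
  prods <- sort(unique(df$product))
  attrs <- unique(df$attribute)
  out <- list()
  for (p in prods) {
    out[[p]] <- list()
    for (a in attrs) {
      sel <- df$product == p & df$attribute == a
      if (!any(sel))
        stop(sprintf("product '%s' is missing attribute series '%s'", p, a))
      tt <- df$time_s[sel]; vv <- df$value[sel]
      nb <- if (is.null(n_basis)) min(length(unique(tt)), 20L) else n_basis
      basis <- make_bspline_basis(min(tt), max(tt), nb, order)
      out[[p]][[a]] <- smooth_penalized(tt, vv, basis, lambda = lambda,
                                        label = paste(p, a, sep = "|"))
    }
  }
  out
}

#' Pointwise Choquet/Shapley importance over a time grid
#'
#' The panel path of temporal drivers of liking: panel ratings are averaged
#' across observers, each product x attribute series (and each product's
#' liking series) is smoothed into a functional curve, the curves are
#' evaluated at every grid time, attribute values are min-max scaled to
#' \[0,1\] across products (they live on incommensurable intensity scales),
#' liking is mapped to \[0,1\] by its declared scale range (it is already
#' commensurable across time points; per-fit min-max over a handful of
#' products would pin the best and worst product to 1 and 0 at every time
#' and distort the response), and a k-additive capacity is identified at
#' each time with [fit_capacity_ls()]. Each fit contributes one row of
#' Shapley values and one row of pairwise interaction indices.
#'
#' With the usual handful of products each pointwise fit is underdetermined
#' (3 observations against 14 free coefficients for 4 attributes at k = 2);
#' the ridge pull toward the uniform additive capacity makes the solution
#' unique and deterministic, and the per-time `underdetermined` flag is kept
#' in the diagnostics.
#'
#' @param panel `mati_dataset` of panel attribute ratings (any scale).
#' @param liking `mati_dataset` of liking for the same products (one
#'   attribute series per product; consumer means for the consumer path).
#' @param times Evaluation grid in seconds (default 3-90 step 3).
#' @param k_additive,ridge Passed to [fit_capacity_ls()].
#' @param n_basis,order,lambda Smoothing settings for the raw series
#'   (defaults: cubic splines, `n_basis = min(#points, 20)`, GCV lambda).
#' @return List with `importance` (an `importance_trajectory`, method
#'   "shapley") and `interactions` (an `interaction_trajectory`).
#' @export
pointwise_importance_choquet <- function(panel, liking,
                                         times = seq(3, 90, by = 3),
                                         k_additive = 2, ridge = 1e-6,
                                         n_basis = NULL, order = 4,
                                         lambda = NULL) {
  stopifnot(inherits(panel, "mati_dataset"), inherits(liking, "mati_dataset"))
  pm <- if (length(unique(panel$observer)) > 1) mati_means(panel) else panel
  lm_ <- if (length(unique(liking$observer)) > 1) mati_means(liking) else liking
  prods <- sort(unique(pm$product))
  if (length(prods) < 2) stop("need at least 2 products")
  attrs <- unique(as.data.frame(pm)$attribute)
  if (length(attrs) < 2) stop("need at least 2 attributes")
  if (!setequal(unique(lm_$product), prods))
    stop("liking must cover the same products as the panel data")

  pc <- smooth_mati_curves(pm, n_basis, order, lambda)
  lc <- smooth_mati_curves(lm_, n_basis, order, lambda)
  lik_attr <- unique(as.data.frame(lm_)$attribute)
  if (length(lik_attr) != 1)
    stop("liking dataset must carry exactly one attribute series")

  dom_lo <- max(vapply(prods, function(p)
    max(vapply(attrs, function(a) pc[[p]][[a]]$basis$domain[1], 0),
        lc[[p]][[lik_attr]]$basis$domain[1]), 0))
  dom_hi <- min(vapply(prods, function(p)
    min(vapply(attrs, function(a) pc[[p]][[a]]$basis$domain[2], 0),
        lc[[p]][[lik_attr]]$basis$domain[2]), 0))
  if (any(times < dom_lo - 1e-9) || any(times > dom_hi + 1e-9))
    stop(sprintf("grid times outside the common curve domain [%g, %g]",
                 dom_lo, dom_hi))

  lik_range <- attr(liking, "scale")$range
  np <- length(attrs)
  sv <- matrix(NA_real_, length(times), np,
               dimnames = list(NULL, attrs))
  iv <- matrix(NA_real_, length(times), np * (np - 1) / 2)
  diags <- vector("list", length(times))
  pair_idx <- utils::combn(np, 2)
  for (ti in seq_along(times)) {
    t <- times[ti]
    X <- sapply(attrs, function(a)
      vapply(prods, function(p) eval_curve(pc[[p]][[a]], t), 0))
    X <- matrix(X, length(prods), np, dimnames = list(prods, attrs))
    y <- vapply(prods, function(p) eval_curve(lc[[p]][[lik_attr]], t), 0)
    sx <- scale_minmax(X)
    ys <- pmin(pmax((y - lik_range[1]) / diff(lik_range), 0), 1)
    fit <- fit_capacity_ls(sx$scaled, ys,
                           k_additive = k_additive, ridge = ridge)
    fit$scaling <- rbind(sx$records,
                         data.frame(variable = "liking",
                                    min = lik_range[1], max = lik_range[2],
                                    constant = FALSE))
    sv[ti, ] <- fit$shapley
    iv[ti, ] <- fit$interactions[cbind(pair_idx[1, ], pair_idx[2, ])]
    diags[[ti]] <- list(residual_sse = fit$residual_sse,
                        underdetermined = fit$underdetermined,
                        scaling = fit$scaling)
  }
  list(importance = importance_trajectory(times, sv, method = "shapley",
                                          diagnostics = diags),
       interactions = interaction_trajectory(times, iv, attrs))
}

#' Pointwise LMG importance over a time grid
#'
#' The consumer path of temporal drivers of liking: at each grid time the
#' consumer x attribute table is regressed on liking and the LMG shares are
#' computed, treating each just-about-right attribute as one 3-level factor
#' group (reference level "just about right"). A time point with
#' zero-variance liking yields a row of missing values with a warning rather
#' than a failure.
#'
#' @param consumer `mati_dataset` of consumer attribute responses (observer =
#'   consumer id; scale "jar" for just-about-right coding).
#' @param liking `mati_dataset` of per-consumer liking at the same times.
#' @param times Evaluation grid in seconds (default 14-90 step 4).
#' @param jar_coding Expand attributes as 3-level JAR factors (default TRUE);
#'   FALSE treats each attribute as one continuous column.
#' @param normalized,seed Passed to [lmg_shares()].
#' @return An `importance_trajectory` (method "lmg") with per-time LMG
#'   diagnostics.
#' @export
pointwise_importance_lmg <- function(consumer, liking,
                                     times = seq(14, 90, by = 4),
                                     jar_coding = TRUE, normalized = TRUE,
                                     seed = 1) {
  stopifnot(inherits(consumer, "mati_dataset"),
            inherits(liking, "mati_dataset"))
  cdf <- as.data.frame(consumer); ldf <- as.data.frame(liking)
  attrs <- unique(cdf$attribute)
  vals <- matrix(NA_real_, length(times), length(attrs),
                 dimnames = list(NULL, attrs))
  diags <- vector("list", length(times))
  for (ti in seq_along(times)) {
    t <- times[ti]
    ct <- cdf[cdf$time_s == t, ]
    lt <- ldf[ldf$time_s == t, ]
    if (!nrow(ct) || !nrow(lt))
      stop(sprintf("no records at grid time %g", t))
    ids <- intersect(unique(ct$observer), unique(lt$observer))
    W <- sapply(attrs, function(a) {
      m <- match(ids, ct$observer[ct$attribute == a])
      ct$value[ct$attribute == a][m]
    })
    W <- matrix(W, length(ids), length(attrs), dimnames = list(ids, attrs))
    y <- lt$value[match(ids, lt$observer)]
    if (stats::var(y) == 0) {
      warning(sprintf("zero-variance liking at time %g s; row left missing", t))
      next
    }
    design <- if (jar_coding) expand_jar_design(W, y)
              else group_design(y, W)
    res <- lmg_shares(design, normalized = normalized, seed = seed)
    vals[ti, names(res$shares)] <- res$shares
    diags[[ti]] <- list(total_r2 = res$total_r2, exact = res$exact,
                        n_orderings_used = res$n_orderings_used)
  }
  importance_trajectory(times, vals, method = "lmg", diagnostics = diags)
}

#' Smooth an importance or interaction trajectory into functional curves
#'
#' One penalized B-spline curve per attribute (or pair), on the domain
#' spanned by the trajectory grid. Smoothing does not enforce the row-sum
#' constraint of importance trajectories exactly; evaluated rows of a
#' Shapley trajectory typically re-sum to 1 within a couple of percent.
#'
#' @param trajectory An `importance_trajectory` or `interaction_trajectory`
#'   with at least 4 time points.
#' @param n_basis,order,lambda Smoothing settings (defaults: cubic,
#'   `min(#times, 20)` basis functions, GCV lambda).
#' @return Named list of `functional_curve`s, one per column.
#' @export
importance_curves <- function(trajectory, n_basis = NULL, order = 4,
                              lambda = NULL) {
  stopifnot(inherits(trajectory, c("importance_trajectory",
                                   "interaction_trajectory")))
  times <- trajectory$times
  if (length(times) < 4) stop("need at least 4 time points")
  nb <- if (is.null(n_basis)) min(length(times), 20L) else n_basis
  basis <- make_bspline_basis(min(times), max(times), nb, order)
  labs <- colnames(trajectory$values)
  out <- lapply(labs, function(lab) {
    v <- trajectory$values[, lab]
    ok <- is.finite(v)
    smooth_penalized(times[ok], v[ok], basis, lambda = lambda, label = lab)
  })
  stats::setNames(out, labs)
}

#' Rebuild a trajectory from smoothed curves
#'
#' Evaluates a set of importance curves back on a grid; optionally
#' renormalizes each row to sum to 1 (off by default — the smoother does not
#' preserve the constraint exactly).
#'
#' @param curves Named list of `functional_curve`s.
#' @param times Evaluation grid.
#' @param method Trajectory method label.
#' @param renormalize Divide each row by its sum (default FALSE).
#' @return An `importance_trajectory`.
#' @export
trajectory_from_curves <- function(curves, times, method = "shapley",
                                   renormalize = FALSE) {
  vals <- sapply(curves, function(cv) eval_curve(cv, times))
  vals <- matrix(vals, length(times), length(curves),
                 dimnames = list(NULL, names(curves)))
  if (renormalize) vals <- vals / rowSums(vals)
  importance_trajectory(times, vals, method = method)
}

#' Dynamics report: extrema and stability of importance curves
#'
#' Evaluates first and second derivatives of each curve on a grid, locates
#' zero crossings of the first derivative by sign change plus bisection
#' refinement (local extrema of the importance measure: a crossing with
#' negative second derivative is a maximum, positive a minimum), and finds
#' maximal stable intervals where both |first| and |second| derivative stay
#' below their thresholds (importance approximately constant in time).
#'
#' @param curves Named list of `functional_curve`s (order >= 4 so both
#'   derivatives are meaningful).
#' @param eval_grid Evaluation grid; default 201 equally spaced points over
#'   the first curve's domain.
#' @param eps1,eps2 Stability thresholds on |d1| and |d2|; default 10% of
#'   each curve's own maximum |d1| and |d2| over the grid.
#' @return A `dynamics_report`: per curve, `crossings` (data frame with
#'   `time`, `type`, `second_deriv`) and `stable` (data frame with `start`,
#'   `end`), plus the thresholds used.
#' @export
derivative_report <- function(curves, eval_grid = NULL, eps1 = NULL,
                              eps2 = NULL) {
  stopifnot(is.list(curves), length(curves) >= 1)
  dom <- curves[[1]]$basis$domain
  if (is.null(eval_grid)) eval_grid <- seq(dom[1], dom[2], length.out = 201)
  per_curve <- lapply(names(curves), function(lab) {
    cv <- curves[[lab]]
    d1 <- eval_curve(cv, eval_grid, deriv = 1)
    d2 <- eval_curve(cv, eval_grid, deriv = 2)
    e1 <- if (is.null(eps1)) 0.1 * max(abs(d1)) else eps1
    e2 <- if (is.null(eps2)) 0.1 * max(abs(d2)) else eps2

    ## zero crossings of d1: sign change between adjacent grid points;
    ## derivatives at numerical-noise level (relative to the curve scale)
    ## count as zero so flat curves report no spurious extrema
    ztol <- 1e-10 * max(1, max(abs(eval_curve(cv, eval_grid))))
    d1z <- d1; d1z[abs(d1z) < ztol] <- 0
    cross_t <- numeric(0); cross_d2 <- numeric(0)
    s <- sign(d1z)
    for (i in seq_len(length(eval_grid) - 1L)) {
      if (s[i] == 0 && i > 1) next
      if (s[i] * s[i + 1L] < 0) {
        root <- stats::uniroot(function(t) eval_curve(cv, t, deriv = 1),
                               lower = eval_grid[i], upper = eval_grid[i + 1L],
                               tol = 1e-10)$root
        cross_t <- c(cross_t, root)
        cross_d2 <- c(cross_d2, eval_curve(cv, root, deriv = 2))
      } else if (s[i + 1L] == 0 && i + 1L < length(eval_grid) &&
                 s[i] * s[i + 2L] < 0) {
        cross_t <- c(cross_t, eval_grid[i + 1L])
        cross_d2 <- c(cross_d2, d2[i + 1L])
      }
    }
    type <- ifelse(cross_d2 < -1e-12, "maximum",
                   ifelse(cross_d2 > 1e-12, "minimum", "flat"))
    stable_mask <- abs(d1) < e1 & abs(d2) < e2
    runs <- rle(stable_mask)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
    keep <- runs$values
    stable <- data.frame(start = eval_grid[starts[keep]],
                         end = eval_grid[ends[keep]])
    list(crossings = data.frame(time = cross_t, type = type,
                                second_deriv = cross_d2),
         stable = stable, eps1 = e1, eps2 = e2)
  })
  structure(stats::setNames(per_curve, names(curves)),
            class = "dynamics_report")
}

#' @export
print.dynamics_report <- function(x, ...) {
  for (lab in names(x)) {
    r <- x[[lab]]
    cat(sprintf("%s: %d extremum(-a)", lab, nrow(r$crossings)))
    if (nrow(r$crossings))
      cat(" at ", paste(sprintf("%.1fs (%s)", r$crossings$time,
                                r$crossings$type), collapse = ", "))
    cat(sprintf("; %d stable interval(s)\n", nrow(r$stable)))
  }
  invisible(x)
}

#' Dominant driver per time point
#'
#' The attribute with the largest importance at each grid time. Exact ties
#' are broken toward the lexicographically first label and flagged.
#'
#' @param trajectory An `importance_trajectory`.
#' @return Data frame with `time`, `driver`, `tie`.
#' @export
dominant_driver <- function(trajectory) {
  stopifnot(inherits(trajectory, "importance_trajectory"))
  V <- trajectory$values
  out <- lapply(seq_len(nrow(V)), function(i) {
    row <- V[i, ]
    mx <- max(row, na.rm = TRUE)
    winners <- sort(names(row)[which(row >= mx - 1e-12)])
    data.frame(time = trajectory$times[i], driver = winners[1],
               tie = length(winners) > 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
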