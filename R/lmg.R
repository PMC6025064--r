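## LMG relative importance: the average over predictor-group orderings of the
## sequential increase in R-squared when a group enters the model after its
## predecessors. Equivalently, the Shapley value of the cooperative game
## whose characteristic function is the R-squared of each group subset.

#' Build a grouped predictor design
#'
#' Groups design columns so a multi-column predictor (e.g., the indicator
#' columns of a 3-level just-about-right factor) is treated as one unit in
#' the ordering average: its importance share is attributed jointly to all
#' its columns.
#'
#' @param response Numeric response (liking), one value per observation.
#' @param columns Numeric design matrix (no intercept column; the intercept
#'   is always included in fits).
#' @param groups Named list mapping each group name to the column indices
#'   (or column names) it owns; every column must belong to exactly one
#'   group. Default: each column is its own group, named after it.
#' @return A `group_design` object.
#' @export
group_design <- function(response, columns, groups = NULL) {
  y <- as.numeric(response)
  X <- as.matrix(columns)
  storage.mode(X) <- "double"
  if (nrow(X) != length(y)) stop("response and columns disagree on n_obs")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(groups))
    groups <- stats::setNames(as.list(seq_len(ncol(X))), colnames(X))
  groups <- lapply(groups, function(g) {
    if (is.character(g)) g <- match(g, colnames(X))
    as.integer(g)
  })
  used <- sort(unname(unlist(groups, use.names = FALSE)))
  if (!identical(used, seq_len(ncol(X))))
    stop("every design column must belong to exactly one group")
  if (nrow(X) <= ncol(X))
    warning("fewer observations than design columns + 1; ",
            "fits use a rank-tolerant least-squares path")
  structure(list(response = y, columns = X, groups = groups,
                 n_obs = length(y)), class = "group_design")
}

#' Expand just-about-right responses into a grouped factor design
#'
#' Each just-about-right (JAR) attribute, coded -1 (too weak), 0 (just about
#' right), +1 (too strong), becomes a 3-level factor with "just about right"
#' as the reference level, contributing one group of indicator columns.
#' LMG shares are invariant to the choice of reference level because the
#' group's column span is unchanged. Attributes with a single observed level
#' carry no variance and are dropped with a warning.
#'
#' @param raw Data frame or matrix, consumers x attributes, values in
#'   \{-1, 0, +1\}.
#' @param response Numeric liking per consumer.
#' @param reference Reference level, one of "0" (default), "-1", "1".
#' @return A `group_design` with one group per retained JAR attribute.
#' @export
expand_jar_design <- function(raw, response, reference = "0") {
  X <- as.matrix(raw)
  if (!all(X %in% c(-1, 0, 1)))
    stop("JAR values must lie in {-1, 0, +1}")
  if (is.null(colnames(X))) colnames(X) <- paste0("jar", seq_len(ncol(X)))
  reference <- match.arg(as.character(reference), c("0", "-1", "1"))
  cols <- list(); groups <- list()
  level_names <- c("-1" = "too_weak", "0" = "just_right", "1" = "too_strong")
  for (a in colnames(X)) {
    lev <- sort(unique(X[, a]))
    if (length(lev) < 2) {
      warning(sprintf("JAR attribute '%s' has a single observed level; dropped", a))
      next
    }
    ref <- if (reference %in% as.character(lev)) as.numeric(reference) else lev[1]
    keep <- setdiff(lev, ref)
    ind <- sapply(keep, function(l) as.numeric(X[, a] == l))
    colnames(ind) <- paste0(a, ".", level_names[as.character(keep)])
    cols[[a]] <- ind
    groups[[a]] <- colnames(ind)
  }
  if (!length(cols)) stop("no JAR attribute with more than one observed level")
  group_design(response, do.call(cbind, cols), groups)
}

## R-squared of regressing y on X plus intercept; rank-deficient designs go
## through a pivoted QR (lm.fit), whose fitted values span the same column
## space as a pseudoinverse fit.
r2_fit <- function(y, X) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(0)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  1 - sum(fit$residuals^2) / sst
}

#' R-squared of a subset of predictor groups
#'
#' Coefficient of determination of the least-squares fit of the response on
#' the union of the subset's columns plus an intercept. The empty subset has
#' R-squared 0.
#'
#' @param design A `group_design`.
#' @param subset Character vector of group names (possibly empty).
#' @return A number in \[0,1\].
#' @export
r2_of_subset <- function(design, subset) {
  stopifnot(inherits(design, "group_design"))
  if (length(subset) == 0) return(0)
  bad <- setdiff(subset, names(design$groups))
  if (length(bad)) stop("unknown group(s): ", paste(bad, collapse = ", "))
  idx <- unlist(design$groups[subset], use.names = FALSE)
  r2_fit(design$response, design$columns[, idx, drop = FALSE])
}

#' LMG relative-importance shares
#'
#' The LMG share of a predictor group is its sequential R-squared increase
#' averaged over all orderings of the groups — the Shapley value of the
#' R-squared game. Unnormalized shares sum to the full-model R-squared;
#' normalized shares sum to 1. Exact enumeration (computed over group
#' subsets with Shapley weights, equivalent to averaging over all orderings)
#' is used up to `max_exact_groups`; beyond that a seeded Monte-Carlo sample
#' of orderings is averaged instead.
#'
#' @param design A `group_design`.
#' @param normalized Divide shares by the full-model R-squared (default
#'   TRUE). Errors if total R-squared is 0.
#' @param max_exact_groups Largest group count fitted by exact enumeration.
#' @param n_sample_orderings Number of Monte-Carlo orderings beyond that.
#' @param seed Integer seed for the Monte-Carlo path (ignored when exact).
#' @return An `lmg_result`: `shares` (named, order-matching the design),
#'   `total_r2`, `normalized`, `n_orderings_used`, `exact`.
#' @references Lindeman, Merenda and Gold's decomposition as popularized for
#'   regression relative importance; equivalent to Shapley-value attribution
#'   of explained variance.
#' @export
lmg_shares <- function(design, normalized = TRUE, max_exact_groups = 8,
                       n_sample_orderings = 10000, seed = 1) {
  stopifnot(inherits(design, "group_design"))
  gnames <- names(design$groups)
  p <- length(gnames)
  if (p < 1) stop("need at least one predictor group")
  if (design$n_obs < 3) stop("need at least 3 observations")

  if (p <= max_exact_groups) {
    ## exact: Shapley weights over group subsets; cache R^2 per subset mask
    r2 <- numeric(2^p)
    for (mask in 1:(2^p - 1L))
      r2[mask + 1L] <- r2_of_subset(design, gnames[bit_members(mask)])
    sizes <- all_mask_sizes(p)
    lf <- lfactorial(0:p)
    shares <- numeric(p)
    for (i in seq_len(p)) {
      bit <- bitwShiftL(1L, i - 1L)
      masks <- which(bitwAnd(0:(2^p - 1L), bit) == 0L) - 1L
      s <- sizes[masks + 1L]
      w <- exp(lf[s + 1L] + lf[p - s] - lf[p + 1L])
      shares[i] <- sum(w * (r2[bitwOr(masks, bit) + 1L] - r2[masks + 1L]))
    }
    n_ord <- factorial(p); exact <- TRUE
  } else {
    shares <- numeric(p)
    rng <- local_rng(seed)
    cache <- new.env(parent = emptyenv())
    r2_cached <- function(mask) {
      key <- as.character(mask)
      got <- get0(key, envir = cache)
      if (!is.null(got)) return(got)
      val <- r2_of_subset(design, gnames[bit_members(mask)])
      assign(key, val, envir = cache)
      val
    }
    for (b in seq_len(n_sample_orderings)) {
      ord <- rng$sample(p)
      mask <- 0L; prev <- 0
      for (i in ord) {
        mask <- bitwOr(mask, bitwShiftL(1L, i - 1L))
        cur <- r2_cached(mask)
        shares[i] <- shares[i] + (cur - prev)
        prev <- cur
      }
    }
    shares <- shares / n_sample_orderings
    n_ord <- n_sample_orderings; exact <- FALSE
  }

  total <- r2_of_subset(design, gnames)
  if (normalized) {
    if (total <= 0) stop("total R-squared is 0; normalized shares undefined")
    shares <- shares / total
  }
  structure(list(shares = stats::setNames(shares, gnames),
                 total_r2 = total, normalized = normalized,
                 n_orderings_used = n_ord, exact = exact),
            class = "lmg_result")
}

#' @export
print.lmg_result <- function(x, ...) {
  cat(sprintf("LMG shares (%s, %s; total R^2 = %.4f)\n",
              if (x$normalized) "normalized" else "unnormalized",
              if (x$exact) "exact" else
                sprintf("%d sampled orderings", x$n_orderings_used),
              x$total_r2))
  print(round(x$shares, 4))
  invisible(x)
}

## Self-contained RNG stream: isolates package randomness from the global
## .Random.seed. Returns closures over a private seed state.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  env$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  with_state <- function(expr) {
    old <- get0(".Random.seed", envir = globalenv())
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", envir = globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    expr
  }
  list(
    sample  = function(n, ...) with_state(sample.int(n, ...)),
    runif   = function(n, min = 0, max = 1) with_state(runif(n, min, max)),
    rnorm   = function(n, mean = 0, sd = 1) with_state(rnorm(n, mean, sd)),
    rmultinom_levels = function(n, prob, levels)
      with_state(levels[sample.int(length(levels), n, replace = TRUE, prob = prob)])
  )
}
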