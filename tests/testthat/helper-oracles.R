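# Independent brute-force oracles and random-object generators shared by the
# unit and acceptance tests. These deliberately avoid the package's own
# transform code paths: Shapley by explicit permutation enumeration,
# interactions by subset enumeration, capacities via the max-of-upper-sets
# construction.

# all permutations of a vector (n <= 6 here)
all_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

# random monotone normalized capacity: v(S) = max over subsets T of S of a
# uniform draw u(T), rescaled to v({}) = 0, v(N) = 1
rand_monotone_capacity <- function(n, attrs = paste0("a", seq_len(n))) {
  u <- runif(2^n); u[1] <- 0
  v <- u
  for (mask in 1:(2^n - 1L)) {
    sub <- mask
    repeat {
      v[mask + 1L] <- max(v[mask + 1L], u[sub + 1L])
      if (sub == 0L) break
      sub <- bitwAnd(sub - 1L, mask)
    }
  }
  v <- (v - v[1]) / (v[2^n] - v[1]); v[1] <- 0; v[2^n] <- 1
  capacity(v, attrs)
}

# Shapley by averaging marginal contributions over every attribute ordering
bf_shapley <- function(cap) {
  n <- length(cap$attributes)
  phi <- numeric(n)
  ps <- all_perms(seq_len(n))
  for (p in ps) {
    mask <- 0L
    for (i in p) {
      m2 <- bitwOr(mask, bitwShiftL(1L, i - 1L))
      phi[i] <- phi[i] + cap$values[m2 + 1L] - cap$values[mask + 1L]
      mask <- m2
    }
  }
  stats::setNames(phi / length(ps), cap$attributes)
}

# pairwise Shapley interaction by explicit weighted subset enumeration of the
# second difference v(S+ij) - v(S+i) - v(S+j) + v(S)
bf_interaction <- function(cap) {
  n <- length(cap$attributes)
  v <- cap$values
  I <- matrix(0, n, n, dimnames = list(cap$attributes, cap$attributes))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    bi <- bitwShiftL(1L, i - 1L); bj <- bitwShiftL(1L, j - 1L)
    acc <- 0
    for (mask in 0:(2^n - 1L)) {
      if (bitwAnd(mask, bitwOr(bi, bj)) != 0L) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
      w <- factorial(s) * factorial(n - s - 2) / factorial(n - 1)
      acc <- acc + w * (v[bitwOr(mask, bitwOr(bi, bj)) + 1L] -
                        v[bitwOr(mask, bi) + 1L] -
                        v[bitwOr(mask, bj) + 1L] + v[mask + 1L])
    }
    I[i, j] <- I[j, i] <- acc
  }
  I
}

# LMG by direct averaging of sequential R^2 gains over all group orderings
bf_lmg <- function(design, normalized = TRUE) {
  gn <- names(design$groups)
  shares <- stats::setNames(numeric(length(gn)), gn)
  ps <- all_perms(gn)
  for (p in ps) {
    prev <- 0; sofar <- character(0)
    for (g in p) {
      sofar <- c(sofar, g)
      cur <- r2_of_subset(design, sofar)
      shares[g] <- shares[g] + cur - prev
      prev <- cur
    }
  }
  shares <- shares / length(ps)
  if (normalized) shares / r2_of_subset(design, gn) else shares
}

# Cox-de Boor recursion, computed independently of splines::splineDesign
cox_de_boor <- function(knots, t, i, k) {
  if (k == 1)
    return(as.numeric(knots[i] <= t & (t < knots[i + 1] ||
             (t == knots[i + 1] && knots[i + 1] == knots[length(knots)]))))
  d1 <- knots[i + k - 1] - knots[i]
  d2 <- knots[i + k] - knots[i + 1]
  a <- if (d1 > 0) (t - knots[i]) / d1 * cox_de_boor(knots, t, i, k - 1) else 0
  b <- if (d2 > 0) (knots[i + k] - t) / d2 * cox_de_boor(knots, t, i + 1, k - 1) else 0
  a + b
}

# the fixed ground-truth 2-additive texture capacity used in recovery tests
truth_mobius_4 <- function(attrs = paste0("Attr", 1:4)) {
  m <- numeric(16)
  m[2^(0:3) + 1] <- c(0.30, 0.17, 0.18, 0.15)
  m[bitwOr(1L, 2L) + 1] <- 0.20
  mobius_capacity(m, attrs, k_additive = 2)
}
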