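test_that("Moebius transform round-trips and matches hand computations", {
  # additive capacity: higher-order coefficients vanish
  v <- capacity(c(0, .5, .5, 1), c("a", "b"))
  m <- to_mobius(v)
  expect_equal(m$coefficients, c(0, .5, .5, 0))
  expect_equal(m$k_additive, 1L)

  # dictator on attribute 1
  vd <- capacity(c(0, 1, 0, 1), c("a", "b"))
  expect_equal(to_mobius(vd)$coefficients, c(0, 1, 0, 0))

  # m({1}) = 1 zeta-transforms to the dictator capacity
  md <- mobius_capacity(c(1, 0, 0), c("a", "b"))
  expect_equal(from_mobius(md)$values, c(0, 1, 0, 1))

  # uniform additive on 3 attributes: v(S) = |S|/3
  mu <- mobius_capacity(c(1/3, 1/3, 0, 1/3, 0, 0, 0), letters[1:3])
  expect_equal(from_mobius(mu)$values,
               c(0, 1, 1, 2, 1, 2, 2, 3) / 3)

  # round trip is exact for random monotone capacities up to n = 6,
  # and the zeta transform agrees with direct subset summation
  set.seed(101)
  for (n in 2:6) {
    for (rep in 1:5) {
      v <- rand_monotone_capacity(n)
      m <- to_mobius(v)
      expect_equal(from_mobius(m)$values, v$values, tolerance = 1e-13)
      # subset-sum oracle for a few masks
      for (mask in sample(0:(2^n - 1L), 4)) {
        acc <- 0; sub <- mask
        repeat {
          acc <- acc + m$coefficients[sub + 1L]
          if (sub == 0L) break
          sub <- bitwAnd(sub - 1L, mask)
        }
        expect_equal(acc, v$values[mask + 1L], tolerance = 1e-12)
      }
    }
  }
})

test_that("invalid capacities are rejected with the violating subsets named", {
  expect_error(capacity(c(0, .6, .4, .9), c("a", "b")), "normalized")
  expect_error(capacity(c(0.1, .6, .4, 1), c("a", "b")), "normalized")
  expect_error(capacity(c(0, .6, .4, .5, .4, 1, .6, 1), letters[1:3],
                        tol = 1e-9),
               "not monotone")
  # raw-map inspection of an infeasible set function
  bad <- capacity(c(0, .6, .4, .5), c("a", "b"), validate = FALSE)
  viol <- check_monotone(bad)
  expect_true(any(viol$subset == "a" & viol$superset == "a+b"))
  # infeasible Moebius vector caught at zeta-transform time
  mbad <- mobius_capacity(c(1.2, 0.5, -0.7), c("a", "b"))
  expect_error(from_mobius(mbad), "not monotone")
})

test_that("check_monotone agrees with an exhaustive all-pairs scan", {
  set.seed(77)
  n <- 4
  for (rep in 1:20) {
    # random signed Moebius-style vectors give plenty of violations
    vals <- c(0, runif(2^n - 2, -0.2, 1), 1)
    v <- capacity(vals, paste0("a", 1:n), validate = FALSE)
    viol <- check_monotone(v, tol = 1e-9)
    # oracle: check every nested pair S < T directly
    any_violation <- FALSE
    for (s in 0:(2^n - 1L)) for (t in 0:(2^n - 1L)) {
      if (s != t && bitwAnd(s, t) == s && vals[s + 1] > vals[t + 1] + 1e-9)
        any_violation <- TRUE
    }
    expect_identical(nrow(viol) > 0, any_violation)
  }
})

test_that("Choquet integral: idempotency, max-capacity, Moebius-min form,
           monotonicity and the additive weighted-mean limit", {
  set.seed(5)
  for (n in c(3, 4, 5)) {
    v <- rand_monotone_capacity(n)
    m <- to_mobius(v)
    # idempotency on constant inputs
    expect_equal(choquet(v, rep(0.37, n)), 0.37, tolerance = 1e-12)
    # the two computation forms agree
    for (rep in 1:10) {
      x <- runif(n)
      expect_equal(choquet(v, x), choquet(m, x), tolerance = 1e-12)
      # bounded by the input range
      expect_gte(choquet(v, x), min(x) - 1e-12)
      expect_lte(choquet(v, x), max(x) + 1e-12)
      # componentwise monotone in x
      x2 <- pmin(x + runif(n, 0, 0.3), 1)
      expect_gte(choquet(v, x2), choquet(v, x) - 1e-12)
    }
  }
  # maximum capacity aggregates to max(x)
  vmax <- capacity(c(0, rep(1, 7)), letters[1:3])
  expect_equal(choquet(vmax, c(.2, .9, .4)), 0.9)
  # additive capacity gives the weighted arithmetic mean
  w <- c(.5, .3, .2)
  vadd <- from_mobius(mobius_capacity(c(w[1], w[2], 0, w[3], 0, 0, 0),
                                      letters[1:3]))
  x <- c(.1, .8, .5)
  expect_equal(choquet(vadd, x), sum(w * x), tolerance = 1e-12)
  # input validation
  expect_error(choquet(vadd, c(.1, .2)), "one per attribute")
  expect_error(choquet(vadd, c(.1, .2, 1.7)), "scale first")
})

test_that("Shapley values match the permutation oracle and are efficient", {
  set.seed(9)
  for (n in 2:5) {
    for (rep in 1:10) {
      v <- rand_monotone_capacity(n)
      phi <- shapley(v)
      expect_equal(sum(phi), 1, tolerance = 1e-10)
      expect_true(all(phi >= -1e-10 & phi <= 1 + 1e-10))
      expect_equal(phi, bf_shapley(v), tolerance = 1e-10)
      # Moebius form agrees with the direct form
      expect_equal(shapley(to_mobius(v)), phi, tolerance = 1e-12)
    }
  }
  # additive capacity: shapley_i = v({i})
  w <- c(.4, .35, .25)
  vadd <- from_mobius(mobius_capacity(c(w[1], w[2], 0, w[3], 0, 0, 0),
                                      letters[1:3]))
  expect_equal(unname(shapley(vadd)), w, tolerance = 1e-12)
})

test_that("permuting the attribute order permutes Shapley values identically", {
  set.seed(31)
  v <- rand_monotone_capacity(4, attrs = c("H", "C", "M", "A"))
  perm <- c(3, 1, 4, 2)
  # rebuild the same set function under the permuted attribute order
  n <- 4
  remap <- function(mask) {
    out <- 0L
    for (i in seq_len(n))
      if (bitwAnd(mask, bitwShiftL(1L, perm[i] - 1L)) != 0L)
        out <- bitwOr(out, bitwShiftL(1L, i - 1L))
    out
  }
  vals2 <- numeric(2^n)
  for (mask in 0:(2^n - 1L)) vals2[remap(mask) + 1L] <- v$values[mask + 1L]
  v2 <- capacity(vals2, v$attributes[perm])
  expect_equal(unname(shapley(v2)), unname(shapley(v)[perm]), tolerance = 1e-12)
})

test_that("interaction indices: symmetry, additive zero, subset-enumeration oracle", {
  set.seed(13)
  for (n in 3:5) {
    v <- rand_monotone_capacity(n)
    I <- interaction_matrix(v)
    expect_equal(I, t(I))
    expect_true(all(diag(I) == 0))
    expect_true(all(I >= -1 - 1e-10 & I <= 1 + 1e-10))
    expect_equal(I, bf_interaction(v), tolerance = 1e-10)
    expect_equal(interaction_matrix(to_mobius(v)), I, tolerance = 1e-12)
  }
  w <- c(.4, .35, .25)
  vadd <- from_mobius(mobius_capacity(c(w[1], w[2], 0, w[3], 0, 0, 0),
                                      letters[1:3]))
  expect_equal(max(abs(interaction_matrix(vadd))), 0, tolerance = 1e-12)
})

test_that("min-max scaling is invertible and flags constant variables", {
  X <- cbind(a = c(0, .25, 1), b = c(10, 40, 20), c = c(7, 7, 7))
  s <- scale_minmax(X)
  expect_equal(s$scaled[, "a"], c(0, .25, 1))       # already spanning [0,1]
  expect_equal(s$scaled[, "c"], rep(0.5, 3))        # constant -> 0.5
  expect_true(s$records$constant[3])
  expect_false(any(s$records$constant[1:2]))
  back <- unscale_minmax(s$scaled, s$records)
  expect_equal(back, X, tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("capacity identification recovers generating capacities", {
  set.seed(7)
  attrs <- paste0("Attr", 1:4)
  X <- matrix(runif(200), 50, 4, dimnames = list(NULL, attrs))

  # realizable additive case: predictions match, interactions vanish
  w <- c(.4, .3, .2, .1)
  y <- as.numeric(X %*% w)
  f <- fit_capacity_ls(X, y, k_additive = 2, ridge = 1e-8)
  expect_lt(f$residual_sse, 1e-12)
  expect_lt(max(abs(f$interactions)), 1e-4)
  expect_equal(unname(f$shapley), w, tolerance = 1e-4)
  expect_false(f$underdetermined)
  expect_equal(sum(f$shapley), 1, tolerance = 1e-10)

  # known 2-additive generator, 50 noiseless samples
  mob <- truth_mobius_4(attrs)
  cap <- from_mobius(mob)
  y2 <- apply(X, 1, function(r) choquet(cap, r))
  f2 <- fit_capacity_ls(X, y2, k_additive = 2, ridge = 1e-8)
  expect_equal(f2$shapley, shapley(mob), tolerance = 1e-4)
  expect_equal(f2$interactions, interaction_matrix(mob), tolerance = 1e-3)

  # the panel setting: 3 samples x 4 attributes is underdetermined but exact
  f3 <- fit_capacity_ls(X[1:3, ], y2[1:3], k_additive = 2, ridge = 1e-6)
  expect_true(f3$underdetermined)
  expect_lt(f3$residual_sse, 1e-8)
  expect_equal(sum(f3$shapley), 1, tolerance = 1e-10)

  # ridge = 0 on an underdetermined problem requires explicit consent
  expect_error(fit_capacity_ls(X[1:3, ], y2[1:3], ridge = 0),
               "no unique optimum")
  f4 <- fit_capacity_ls(X[1:3, ], y2[1:3], ridge = 0,
                        allow_underdetermined = TRUE)
  expect_lt(f4$residual_sse, 1e-8)
})

test_that("the penalized objective never improves when ridge grows", {
  set.seed(21)
  attrs <- paste0("A", 1:4)
  X <- matrix(runif(120), 30, 4, dimnames = list(NULL, attrs))
  cap <- from_mobius(truth_mobius_4(attrs))
  y <- apply(X, 1, function(r) choquet(cap, r)) + rnorm(30, 0, 0.05)
  y <- pmin(pmax(y, 0), 1)
  sse <- sapply(c(1e-8, 1e-4, 1e-1, 1), function(r)
    fit_capacity_ls(X, y, ridge = r)$residual_sse)
  expect_true(all(diff(sse) >= -1e-10))
})

test_that("capacities serialize to JSON and back bit-exactly", {
  set.seed(4)
  v <- rand_monotone_capacity(4, attrs = c("H", "C", "M", "A"))
  v2 <- capacity_from_json(capacity_to_json(v))
  expect_identical(v2$values, v$values)
  expect_identical(v2$attributes, v$attributes)
  m <- to_mobius(v)
  m2 <- capacity_from_json(capacity_to_json(m))
  expect_identical(m2$coefficients, m$coefficients)
  expect_identical(m2$k_additive, m$k_additive)
})
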