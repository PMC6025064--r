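make_correlated_design <- function(n = 40, seed = 3) {
  set.seed(seed)
  X <- matrix(rnorm(n * 3), n, 3)
  X[, 2] <- 0.6 * X[, 1] + 0.8 * X[, 2]   # deliberate collinearity
  colnames(X) <- c("a", "b", "c")
  y <- X %*% c(1, 0.5, 0.2) + rnorm(n, 0, 0.5)
  group_design(y, X)
}

test_that("r2_of_subset matches independent computations", {
  d <- make_correlated_design()
  expect_identical(r2_of_subset(d, character(0)), 0)
  # equals the squared correlation between response and fitted values
  for (sub in list("a", c("a", "b"), c("a", "b", "c"))) {
    fit <- lm(d$response ~ d$columns[, unlist(d$groups[sub])])
    expect_equal(r2_of_subset(d, sub),
                 cor(d$response, fitted(fit))^2, tolerance = 1e-10)
  }
  # exactly linear response gives R^2 = 1
  dlin <- group_design(d$columns %*% c(2, -1, 3), d$columns)
  expect_equal(r2_of_subset(dlin, c("a", "b", "c")), 1, tolerance = 1e-12)
  expect_error(r2_of_subset(d, "nope"), "unknown group")
})

test_that("LMG shares equal the full ordering enumeration and decompose R^2", {
  d <- make_correlated_design()
  res <- lmg_shares(d, normalized = FALSE)
  expect_true(res$exact)
  expect_equal(res$n_orderings_used, 6)
  # full-enumeration oracle
  expect_equal(res$shares, bf_lmg(d, normalized = FALSE), tolerance = 1e-12)
  # decomposition: unnormalized shares sum to the full-model R^2
  expect_equal(sum(res$shares), res$total_r2, tolerance = 1e-10)
  # nonnegativity (R^2 is monotone in nested least-squares models)
  expect_true(all(res$shares >= -1e-12))
  # normalized shares sum to 1
  resn <- lmg_shares(d, normalized = TRUE)
  expect_equal(sum(resn$shares), 1, tolerance = 1e-10)
  # single group: share = that regression's R^2
  d1 <- group_design(d$response, d$columns[, 1, drop = FALSE])
  r1 <- lmg_shares(d1, normalized = FALSE)
  expect_equal(unname(r1$shares), r2_of_subset(d1, names(d1$groups)),
               tolerance = 1e-12)
})

test_that("orthogonal predictors get their marginal R^2 as share", {
  # two exactly orthogonal centered columns: order does not matter
  x1 <- c(1, 1, -1, -1, 0, 0); x2 <- c(1, -1, 1, -1, 0, 0)
  y <- 2 * x1 + x2 + c(.1, -.1, .05, -.05, .2, -.2)
  d <- group_design(y, cbind(a = x1, b = x2))
  res <- lmg_shares(d, normalized = FALSE)
  expect_equal(unname(res$shares["a"]), r2_of_subset(d, "a"), tolerance = 1e-12)
  expect_equal(unname(res$shares["b"]), r2_of_subset(d, "b"), tolerance = 1e-12)
})

test_that("LMG is the Shapley value of the normalized R-squared game", {
  # cross-module identity: build a capacity whose subset values are
  # R^2(S) / R^2(full) and compare its Shapley vector with the LMG shares
  d <- make_correlated_design(n = 50, seed = 8)
  gn <- names(d$groups)
  total <- r2_of_subset(d, gn)
  vals <- vapply(0:(2^3 - 1L), function(mask) {
    members <- gn[which(bitwAnd(mask, bitwShiftL(1L, 0:2)) != 0L)]
    r2_of_subset(d, members) / total
  }, 0)
  game <- capacity(vals, gn)
  res <- lmg_shares(d, normalized = TRUE)
  expect_equal(res$shares, shapley(game), tolerance = 1e-10)
})

test_that("group input order does not change the shares", {
  d <- make_correlated_design()
  dperm <- group_design(d$response, d$columns[, c(3, 1, 2)])
  res <- lmg_shares(d)
  resp <- lmg_shares(dperm)
  expect_equal(resp$shares[names(res$shares)], res$shares, tolerance = 1e-12)
})

test_that("Monte-Carlo ordering sampling converges to the exact shares", {
  set.seed(44)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5)
  X[, 2] <- X[, 1] + 0.5 * X[, 2]
  X[, 4] <- X[, 3] - 0.5 * X[, 4]
  colnames(X) <- paste0("g", 1:5)
  y <- X %*% c(1, .8, .6, .4, .2) + rnorm(n)
  d <- group_design(y, X)
  exact <- lmg_shares(d)
  mc <- lmg_shares(d, max_exact_groups = 2, n_sample_orderings = 10000,
                   seed = 99)
  expect_false(mc$exact)
  expect_lt(max(abs(mc$shares - exact$shares)), 0.01)
  # seeded: same seed reproduces the same shares
  mc2 <- lmg_shares(d, max_exact_groups = 2, n_sample_orderings = 10000,
                    seed = 99)
  expect_identical(mc$shares, mc2$shares)
})

test_that("JAR expansion builds one indicator group per attribute", {
  set.seed(4)
  J <- matrix(sample(c(-1, 0, 1), 120, TRUE), 40, 3,
              dimnames = list(NULL, c("FruitFlavor", "Sweetness", "Sourness")))
  y <- 70 - 25 * (J[, 2] != 0) - 10 * (J[, 1] != 0) + rnorm(40, 0, 5)
  d <- expand_jar_design(J, y)
  expect_length(d$groups, 3)
  expect_equal(ncol(d$columns), 6)            # 3 attributes x 2 non-reference levels
  expect_equal(lengths(d$groups), c(FruitFlavor = 2L, Sweetness = 2L,
                                    Sourness = 2L))
  # shares are invariant to the reference level (same column span)
  r0 <- lmg_shares(d)
  rw <- lmg_shares(expand_jar_design(J, y, reference = "-1"))
  expect_equal(rw$shares, r0$shares, tolerance = 1e-10)
  # a degenerate all-just-right attribute is dropped with a warning
  J2 <- cbind(J, Flat = 0)
  expect_warning(d2 <- expand_jar_design(J2, y), "single observed level")
  expect_length(d2$groups, 3)
  expect_error(expand_jar_design(cbind(bad = c(2, 0, 1)), 1:3), "\\{-1, 0, \\+1\\}")
})

test_that("degenerate responses are refused where shares are undefined", {
  X <- cbind(a = rnorm(20), b = rnorm(20))
  d <- group_design(rep(5, 20), X)        # zero-variance response
  expect_error(lmg_shares(d, normalized = TRUE), "undefined")
  r <- lmg_shares(d, normalized = FALSE)  # unnormalized shares are all 0
  expect_equal(unname(r$shares), c(0, 0))
})
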