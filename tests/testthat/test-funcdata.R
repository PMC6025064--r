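test_that("basis construction and the partition-of-unity property", {
  # order 4, n_basis 4: plain cubic polynomial space, no interior knots
  b0 <- make_bspline_basis(0, 1, 4, 4)
  expect_length(b0$interior_knots, 0)
  b <- make_bspline_basis(3, 90, 12, 4)
  expect_length(b$interior_knots, 8)
  tt <- seq(3, 90, length.out = 100)
  expect_lt(max(abs(rowSums(eval_basis(b, tt)) - 1)), 1e-12)
  expect_error(make_bspline_basis(0, 1, 3, 4), "n_basis")
  expect_error(make_bspline_basis(1, 1, 4, 4), "t_max")
})

test_that("basis values match an independent Cox-de Boor recursion", {
  b <- make_bspline_basis(0, 10, 9, 4)
  set.seed(2)
  tt <- runif(50, 0, 10)
  B <- eval_basis(b, tt)
  for (j in seq_len(b$n_basis)) {
    oracle <- vapply(tt, function(t) cox_de_boor(b$knots, t, j, b$order), 0)
    expect_equal(B[, j], oracle, tolerance = 1e-12)
  }
})

test_that("smoothing limits: interpolation at lambda 0, straight line at
           heavy penalty, and the direct normal-equations oracle", {
  tt <- seq(0, 10, length.out = 12)
  y <- sin(tt)
  # lambda = 0 with n_basis = number of points interpolates
  bi <- make_bspline_basis(0, 10, 12, 4)
  ci <- smooth_penalized(tt, y, bi, lambda = 0)
  expect_lt(max(abs(eval_curve(ci, tt) - y)), 1e-8)

  # heavy penalty shrinks to the least-squares straight line
  tg <- seq(0, 10, length.out = 100)
  yg <- sin(tg)
  bg <- make_bspline_basis(0, 10, 12, 4)
  ch <- smooth_penalized(tg, yg, bg, lambda = 1e9)
  line <- fitted(lm(yg ~ tg))
  expect_lt(max(abs(eval_curve(ch, tg) - line)), 1e-3)

  # coefficients equal the direct solution of the penalized normal equations
  # with the curvature penalty assembled by independent adaptive quadrature
  bsm <- make_bspline_basis(0, 10, 6, 4)
  lam <- 2.5
  B <- eval_basis(bsm, tg)
  R <- matrix(0, 6, 6)
  for (i in 1:6) for (j in i:6) {
    f <- function(t) eval_basis(bsm, t, deriv = 2)[, i] *
                     eval_basis(bsm, t, deriv = 2)[, j]
    R[i, j] <- R[j, i] <- stats::integrate(f, 0, 10, rel.tol = 1e-12,
                                           subdivisions = 400L)$value
  }
  oracle_coefs <- solve(crossprod(B) + lam * R, crossprod(B, yg))
  cv <- smooth_penalized(tg, yg, bsm, lambda = lam)
  expect_equal(cv$coefficients, as.numeric(oracle_coefs), tolerance = 1e-8)
})

test_that("GCV picks a lambda that tracks a smooth signal", {
  set.seed(6)
  tt <- seq(3, 90, by = 3)
  y <- 0.3 + 0.1 * sin(2 * pi * tt / 60) + rnorm(length(tt), 0, 0.01)
  b <- make_bspline_basis(3, 90, 20, 4)
  cv <- smooth_penalized(tt, y, b)       # lambda from GCV
  expect_true(cv$lambda > 0)
  expect_lt(mean(abs(eval_curve(cv, tt) - (0.3 + 0.1 * sin(2 * pi * tt / 60)))),
            0.01)
})

test_that("curve evaluation, derivatives and the no-extrapolation rule", {
  b <- make_bspline_basis(0, 10, 10, 4)
  tt <- seq(0, 10, length.out = 60)
  cv <- smooth_penalized(tt, sin(tt), b, lambda = 1e-6)
  # constant curve has zero first derivative
  cc <- smooth_penalized(tt, rep(2.5, 60), b, lambda = 1)
  expect_lt(max(abs(eval_curve(cc, tt, deriv = 1))), 1e-8)
  # derivative matches central finite differences (relative 1e-4)
  t0 <- seq(0.5, 9.5, length.out = 30); h <- 1e-4
  fd <- (eval_curve(cv, t0 + h) - eval_curve(cv, t0 - h)) / (2 * h)
  d1 <- eval_curve(cv, t0, deriv = 1)
  expect_lt(max(abs(d1 - fd) / pmax(abs(fd), 1)), 1e-4)
  # second derivative likewise
  fd2 <- (eval_curve(cv, t0 + h, 1) - eval_curve(cv, t0 - h, 1)) / (2 * h)
  expect_lt(max(abs(eval_curve(cv, t0, 2) - fd2) / pmax(abs(fd2), 1)), 1e-4)
  # integral of the first derivative telescopes to curve differences
  intd1 <- stats::integrate(function(t) eval_curve(cv, t, 1), 2, 8,
                            rel.tol = 1e-10)$value
  expect_equal(intd1, eval_curve(cv, 8) - eval_curve(cv, 2), tolerance = 1e-6)
  # domain errors
  expect_error(eval_curve(cv, 10.5), "domain")
  expect_error(eval_curve(cv, -0.1), "domain")
})

test_that("smoothing is linear and bitwise reproducible", {
  tt <- seq(0, 20, by = 0.5)
  b <- make_bspline_basis(0, 20, 15, 4)
  set.seed(8)
  y1 <- rnorm(length(tt)); y2 <- rnorm(length(tt))
  lam <- 0.7
  c1 <- smooth_penalized(tt, y1, b, lambda = lam)
  c2 <- smooth_penalized(tt, y2, b, lambda = lam)
  c12 <- smooth_penalized(tt, y1 + y2, b, lambda = lam)
  expect_equal(c12$coefficients, c1$coefficients + c2$coefficients,
               tolerance = 1e-10)
  # identical inputs give bitwise identical coefficients
  c1b <- smooth_penalized(tt, y1, b, lambda = lam)
  expect_identical(c1$coefficients, c1b$coefficients)
  # degenerate input errors
  expect_error(smooth_penalized(c(5, 5, 5), c(1, 2, 3), b), "distinct times")
  expect_error(smooth_penalized(tt, c(y1[-1], NA), b), "finite")
})

test_that("curves serialize to JSON and restore bit-exactly", {
  tt <- seq(3, 90, by = 3)
  b <- make_bspline_basis(3, 90, 14, 4)
  cv <- smooth_penalized(tt, sqrt(tt), b, label = "demo")
  cv2 <- curve_from_json(curve_to_json(cv))
  expect_identical(cv2$coefficients, cv$coefficients)
  expect_identical(cv2$basis$knots, cv$basis$knots)
  expect_identical(cv2$label, "demo")
  expect_identical(eval_curve(cv2, tt), eval_curve(cv, tt))
})
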