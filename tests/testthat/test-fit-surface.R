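test_that("an exact two-level image fits with zero surface and zero cost", {
  img <- two_level_image(8, 8, 0.3, 0.7)
  bp <- fuzzy_bipartition(img, cell_size = 4)
  fit <- fit_surface(img, bp, degree = 2)
  expect_equal(fit$mu_F, 0.3, tolerance = 1e-12)
  expect_equal(fit$mu_B, 0.7, tolerance = 1e-12)
  expect_true(all(abs(fit$surface$coefficients) < 1e-10))
  expect_lt(fit$epsilon2, 1e-20)
})

test_that("noiseless linear bias is recovered exactly", {
  cc <- pixel_coords(16, 16)
  base <- ifelse(cbind(matrix(TRUE, 16, 8), matrix(FALSE, 16, 8)), 0.3, 0.7)
  img <- base + 0.1 * cc$x + 0.05 * cc$y
  bp <- fuzzy_bipartition(img, cell_size = 4)
  fit <- fit_surface(img, bp, degree = 1)
  expect_equal(unname(fit$surface$coefficients), c(0.1, 0.05),
               tolerance = 1e-10)
  expect_equal(fit$mu_F, 0.3, tolerance = 1e-10)
  expect_equal(fit$mu_B, 0.7, tolerance = 1e-10)
})

test_that("noisy coefficient estimates concentrate on the generating values", {
  # Monte-Carlo oracle: the generating parameters themselves
  set.seed(123)
  cc <- pixel_coords(16, 16)
  mask_f <- cbind(matrix(TRUE, 16, 8), matrix(FALSE, 16, 8))
  base <- ifelse(mask_f, 0.3, 0.7)
  bp <- list(hard_labels = ifelse(mask_f, "F", "B"))
  est <- t(replicate(100, {
    img <- base + 0.1 * cc$x + 0.05 * cc$y + matrix(rnorm(256, 0, 0.01), 16)
    unname(fit_surface(img, bp, degree = 1)$surface$coefficients)
  }))
  se_mean <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_true(all(abs(colMeans(est) - c(0.1, 0.05)) < 3 * se_mean))
})

test_that("epsilon2 is the mean squared residual of the returned parameters", {
  set.seed(9)
  for (rep in 1:5) {
    img <- matrix(runif(144, 0.2, 0.8), 12, 12)
    bp <- fuzzy_bipartition(img, cell_size = 4)
    fit <- fit_surface(img, bp, degree = 2)
    mu <- ifelse(bp$hard_labels == "F", fit$mu_F, fit$mu_B)
    p <- eval_surface(fit$surface, nrow = 12, ncol = 12)
    expect_equal(fit$epsilon2, mean((img - mu - p)^2), tolerance = 1e-12)
  }
})

test_that("raising the surface degree never increases the fitted cost", {
  set.seed(31)
  img <- matrix(runif(256, 0.2, 0.8), 16, 16)
  bp <- fuzzy_bipartition(img, cell_size = 4)
  eps <- vapply(1:4, function(d) fit_surface(img, bp, d)$epsilon2, numeric(1))
  expect_true(all(diff(eps) <= 1e-12))
})

test_that("joint least squares matches a brute-force grid minimization", {
  # 8x8 image with degree-1 bias; oracle = exhaustive search over
  # (mu_F, mu_B, c_x, c_y) on a grid around the generating values
  set.seed(5)
  cc <- pixel_coords(8, 8)
  mask_f <- cbind(matrix(TRUE, 8, 4), matrix(FALSE, 8, 4))
  img <- ifelse(mask_f, 0.35, 0.65) + 0.08 * cc$x - 0.05 * cc$y +
    matrix(rnorm(64, 0, 0.005), 8, 8)
  bp <- list(hard_labels = ifelse(mask_f, "F", "B"))
  fit <- fit_surface(img, bp, degree = 1)

  step <- 0.005
  grid <- expand.grid(muF = seq(0.33, 0.37, step),
                      muB = seq(0.63, 0.67, step),
                      cx = seq(0.06, 0.10, step),
                      cy = seq(-0.07, -0.03, step))
  cost <- vapply(seq_len(nrow(grid)), function(i) {
    mu <- ifelse(mask_f, grid$muF[i], grid$muB[i])
    mean((img - mu - grid$cx[i] * cc$x - grid$cy[i] * cc$y)^2)
  }, numeric(1))
  best <- grid[which.min(cost), ]
  # analytic minimum can only undercut the grid minimum
  expect_lte(fit$epsilon2, min(cost) + 1e-15)
  # and the argmin agrees to grid resolution
  expect_lt(max(abs(c(fit$mu_F, fit$mu_B, fit$surface$coefficients) -
                  c(best$muF, best$muB, best$cx, best$cy))), step)
})

test_that("degenerate bipartitions and invalid degrees are rejected", {
  img <- two_level_image()
  bp_empty <- list(hard_labels = matrix("B", 8, 8))
  expect_error(fit_surface(img, bp_empty, 2),
               class = "sonodae_degenerate_bipartition")
  bp <- fuzzy_bipartition(img, cell_size = 4)
  expect_error(fit_surface(img, bp, 0), "between 1 and 4")
  expect_error(fit_surface(img, bp, 5), "between 1 and 4")
})
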