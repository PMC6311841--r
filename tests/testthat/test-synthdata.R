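test_that("a zero-amplitude mask is the exact ellipse membership test", {
  spec <- phantom_spec(class_label = "benign", lesion_axes = c(6, 4),
                      margin_amplitude = 0, seed = 1)
  mask <- lesion_mask(spec)
  cx <- spec$lesion_center[1]; cy <- spec$lesion_center[2]
  oracle <- outer(seq_len(28), seq_len(28), function(r, c)
    ((c - cx) / 6)^2 + ((r - cy) / 4)^2 < 1)
  expect_equal(mask, oracle)
})

test_that("margin irregularity lengthens the lesion boundary", {
  boundary_len <- function(mask) {
    pad <- rbind(FALSE, cbind(FALSE, mask, FALSE), FALSE)
    nr <- nrow(pad); nc <- ncol(pad)
    core <- pad[2:(nr - 1), 2:(nc - 1)]
    nb_bg <- !pad[1:(nr - 2), 2:(nc - 1)] | !pad[3:nr, 2:(nc - 1)] |
      !pad[2:(nr - 1), 1:(nc - 2)] | !pad[2:(nr - 1), 3:nc]
    sum(core & nb_bg)
  }
  smooth <- phantom_spec(class_label = "benign", lesion_axes = c(6, 4),
                         seed = 2)
  lobed <- phantom_spec(class_label = "malignant", lesion_axes = c(6, 4),
                        margin_amplitude = 0.25, margin_lobes = 7,
                        boundary_dropout = 0, seed = 2)
  expect_gt(boundary_len(lesion_mask(lobed)), boundary_len(lesion_mask(smooth)))
})

test_that("phantom rendering is deterministic and leaves the global stream alone", {
  spec <- phantom_spec(class_label = "malignant", seed = 123)
  expect_identical(lesion_mask(spec), lesion_mask(spec))
  a <- render_phantom(spec)
  set.seed(77)
  before <- runif(3)
  b <- render_phantom(spec)
  set.seed(77)
  expect_identical(runif(3), before)  # stream untouched by rendering
  expect_identical(a$image, b$image)
})

test_that("noise-free, bias-free benign phantoms are exact two-level ellipses", {
  spec <- phantom_spec(class_label = "benign", speckle_sigma = 0,
                       margin_amplitude = 0, seed = 5)
  ph <- render_phantom(spec)
  expect_true(all(ph$bias_field == 0))
  expect_equal(sort(unique(as.vector(ph$image))), c(0.3, 0.65))
  expect_equal(ph$image[ph$mask], rep(0.3, sum(ph$mask)),
               ignore_attr = TRUE)
})

test_that("the injected bias field is exactly what rendering adds", {
  plane <- polynomial_surface(c(0.1, 0, 0, 0, 0), 2)
  spec <- phantom_spec(class_label = "benign", speckle_sigma = 0,
                       bias = plane, seed = 9)
  spec0 <- phantom_spec(class_label = "benign", speckle_sigma = 0,
                        bias = NULL, seed = 9)
  delta <- render_phantom(spec)$image - render_phantom(spec0)$image
  truth <- eval_surface(plane, nrow = 28, ncol = 28)
  expect_equal(mean(delta), 0, tolerance = 1e-12)  # plane has zero grid mean
  expect_gt(cor(as.vector(delta), as.vector(truth)), 0.99)
})

test_that("regression on the design matrix recovers injected coefficients", {
  coef <- c(0.06, -0.04, 0.05, 0.03, -0.05)
  spec <- phantom_spec(class_label = "malignant", speckle_sigma = 0,
                       bias = polynomial_surface(coef, 2), seed = 31)
  ph <- render_phantom(spec)
  resid <- as.vector(ph$image - ph$speckled)
  cc <- pixel_coords(28, 28)
  X <- build_design_matrix(cbind(as.vector(cc$x), as.vector(cc$y)), 2)
  fit <- lm.fit(X, resid)
  expect_equal(unname(fit$coefficients), coef, tolerance = 1e-10)
  r2 <- 1 - sum(fit$residuals^2) / sum((resid - mean(resid))^2)
  expect_gt(r2, 0.99)
})

test_that("dataset splits are stratified with exact sizes", {
  ds <- make_dataset(74, 96, 27 / 170, seed = 2, bias_strength = 0.15)
  expect_length(ds$test$labels, 27)
  expect_length(ds$train$labels, 143)
  expect_equal(sum(ds$test$labels), 15)       # largest-remainder malignant quota
  expect_equal(sum(ds$train$labels), 96 - 15)
  expect_true(all(vapply(ds$train$images, function(m)
    all(dim(m) == c(28, 28)), logical(1))))
  # BUSIS-style split: 250 -> 210/40, 16/24 by class
  q <- sonodae:::split_quota(c(benign = 100, malignant = 150), 40)
  expect_equal(unname(q), c(16, 24))
})

test_that("dataset generation is reproducible to the byte on disk", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_dataset(4, 4, 0.5, seed = 4, bias_strength = 0.1, out_dir = d1)
  make_dataset(4, 4, 0.5, seed = 4, bias_strength = 0.1, out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(all(c("b001.png", "labels.csv", "truth/b001_bias.tif") %in% f1))
  expect_identical(f1, list.files(d2, recursive = TRUE))
  h1 <- tools::md5sum(file.path(d1, f1))
  h2 <- tools::md5sum(file.path(d2, f1))
  expect_identical(unname(h1), unname(h2))
  labels <- read.csv(file.path(d1, "labels.csv"))
  expect_equal(nrow(labels), 8)
  expect_equal(sort(unique(labels$label)), c("benign", "malignant"))
})

test_that("invalid specs and splits are rejected", {
  expect_error(phantom_spec(class_label = "benign",
                            lesion_center = c(3, 3), lesion_axes = c(6, 4)),
               "does not fit")
  expect_error(phantom_spec(class_label = "benign", mu_lesion = 0.7,
                            mu_background = 0.6), "hypoechoic")
  expect_error(make_dataset(1, 2, 0.5, seed = 1), "at least 4")
  expect_error(make_dataset(2, 2, 0.25, seed = 1), "at least 2")
})

test_that("written images survive the PNG round trip at 8-bit precision", {
  d <- withr::local_tempdir()
  ds <- make_dataset(4, 4, 0.5, seed = 6, out_dir = d)
  img <- read_gray_image(file.path(d, "m001.png"))
  side <- if ("m001" %in% ds$train$ids) ds$train else ds$test
  idx <- which(side$ids == "m001")
  expect_lt(max(abs(img - side$images[[idx]])), 1 / 255)
  # bias truth TIFF stores (P + 1) / 2 in float precision
  tru <- 2 * tiff::readTIFF(file.path(d, "truth", "m001_bias.tif")) - 1
  expect_lt(max(abs(tru - side$bias_fields[[idx]])), 1e-6)
})
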