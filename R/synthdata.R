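# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so phantom rendering never perturbs training
# randomness.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic lesion ROI phantom
#'
#' A phantom is a hypoechoic (dark) lesion on a brighter background,
#' observed through multiplicative speckle and an additive low-order
#' polynomial bias field — the same generative structure the correction
#' model assumes. Benign lesions have a smooth elliptical margin; malignant
#' ones get a lobulated margin (sinusoidal radial perturbation) and
#' optionally a missing-boundary arc where the margin contrast is erased.
#'
#' @param size Image side length in pixels. Default 28.
#' @param class_label `"benign"` or `"malignant"`.
#' @param lesion_center `(x, y)` center in pixel units (1-based, x along
#'   columns). Default: image center.
#' @param lesion_axes `(a, b)` semi-axes in pixels (x and y). Default
#'   `c(6, 4)`.
#' @param margin_amplitude Radial perturbation amplitude `A >= 0`; the
#'   margin radius is `r0(theta) * (1 + A * sin(K * theta + phi))` with a
#'   seeded phase `phi`. Defaults: 0 (benign), 0.25 (malignant).
#' @param margin_lobes Lobe count `K >= 0`. Defaults: 0 (benign),
#'   7 (malignant).
#' @param mu_lesion,mu_background Mean intensities in \[0, 1\] with
#'   `mu_lesion < mu_background`. Defaults 0.3 and 0.65.
#' @param speckle_sigma Log-normal multiplicative speckle scale.
#'   Default 0.05.
#' @param bias A `polynomial_surface` to inject (zero constant term), or
#'   `NULL` for no bias.
#' @param boundary_dropout Fraction of the margin arc (0 to 1) whose
#'   lesion/background contrast is erased. Defaults: 0 (benign),
#'   0.2 (malignant).
#' @param seed Integer seed controlling the margin phase, dropout arc
#'   position and speckle.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 28,
                         class_label = c("benign", "malignant"),
                         lesion_center = NULL, lesion_axes = c(6, 4),
                         margin_amplitude = NULL, margin_lobes = NULL,
                         mu_lesion = 0.3, mu_background = 0.65,
                         speckle_sigma = 0.05, bias = NULL,
                         boundary_dropout = NULL, seed = 1L) {
  class_label <- match.arg(class_label)
  malignant <- class_label == "malignant"
  if (is.null(lesion_center)) lesion_center <- rep((size + 1) / 2, 2)
  if (is.null(margin_amplitude)) margin_amplitude <- if (malignant) 0.25 else 0
  if (is.null(margin_lobes)) margin_lobes <- if (malignant) 7L else 0L
  if (is.null(boundary_dropout)) boundary_dropout <- if (malignant) 0.2 else 0
  if (mu_lesion >= mu_background)
    stop("lesion must be hypoechoic: mu_lesion < mu_background",
         call. = FALSE)
  if (mu_lesion < 0 || mu_background > 1)
    stop("intensities must lie in [0, 1]", call. = FALSE)
  if (margin_amplitude < 0 || margin_lobes < 0 || boundary_dropout < 0 ||
      boundary_dropout > 1 || speckle_sigma < 0)
    stop("invalid phantom parameters", call. = FALSE)
  spec <- structure(list(size = as.integer(size), class_label = class_label,
                         lesion_center = as.numeric(lesion_center),
                         lesion_axes = as.numeric(lesion_axes),
                         margin_amplitude = margin_amplitude,
                         margin_lobes = as.integer(margin_lobes),
                         mu_lesion = mu_lesion,
                         mu_background = mu_background,
                         speckle_sigma = speckle_sigma, bias = bias,
                         boundary_dropout = boundary_dropout,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  max_r <- max(lesion_axes) * (1 + margin_amplitude)
  if (any(lesion_center - max_r < 1) || any(lesion_center + max_r > size))
    stop("lesion does not fit inside the image", call. = FALSE)
  spec
}

# Per-pixel polar geometry about the lesion center: angle, radius, and the
# (possibly perturbed) margin radius r(theta).
phantom_geometry <- function(spec, phi) {
  cx <- spec$lesion_center[1]; cy <- spec$lesion_center[2]
  a <- spec$lesion_axes[1]; b <- spec$lesion_axes[2]
  dx <- matrix(seq_len(spec$size), spec$size, spec$size, byrow = TRUE) - cx
  dy <- matrix(seq_len(spec$size), spec$size, spec$size) - cy
  theta <- atan2(dy, dx)
  r0 <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  rb <- r0 * (1 + spec$margin_amplitude *
                sin(spec$margin_lobes * theta + phi))
  list(theta = theta, radius = sqrt(dx^2 + dy^2), boundary = rb)
}

#' Binary lesion mask of a phantom
#'
#' A pixel belongs to the lesion iff its polar radius about the center is
#' strictly less than `r(theta) = r0(theta) * (1 + A * sin(K * theta +
#' phi))`, where `r0` is the exact ellipse radius and the phase `phi` is
#' drawn from the phantom's seed.
#'
#' @param spec A [phantom_spec()].
#' @return Logical `size x size` matrix.
#' @export
lesion_mask <- function(spec) {
  phi <- with_seed(spec$seed, stats::runif(1) * 2 * pi)
  g <- phantom_geometry(spec, phi)
  g$radius < g$boundary
}

#' Render a phantom image
#'
#' Builds the clean two-level image from the mask, erases the margin along
#' the seeded dropout arc (malignant missing-boundary artifact), applies
#' multiplicative log-normal speckle `clean * exp(N(0, sigma^2))`
#' (rescaled by `exp(sigma^2/2)` so speckle is mean-preserving), adds the
#' injected polynomial bias field, and clips to \[0, 1\].
#'
#' @param spec A [phantom_spec()].
#' @return A list: `image` (final `gray_image`), `class_label`, `label`
#'   (1 = malignant), `bias_field` (the exact injected surface on the
#'   grid), `mask`, `clean` (two-level image after dropout, before
#'   speckle/bias), `speckled` (after speckle, before bias — the bias-free
#'   reference).
#' @export
render_phantom <- function(spec) {
  draws <- with_seed(spec$seed, {
    phi <- stats::runif(1) * 2 * pi
    theta0 <- stats::runif(1) * 2 * pi
    noise <- matrix(stats::rnorm(spec$size^2, 0, spec$speckle_sigma),
                    spec$size, spec$size)
    list(phi = phi, theta0 = theta0, noise = noise)
  })
  g <- phantom_geometry(spec, draws$phi)
  mask <- g$radius < g$boundary
  clean <- spec$mu_lesion * mask + spec$mu_background * !mask

  if (spec$boundary_dropout > 0) {
    arc <- (g$theta - draws$theta0) %% (2 * pi) <
      spec$boundary_dropout * 2 * pi
    band <- arc & mask & (g$radius > g$boundary - 2)
    clean[band] <- spec$mu_background
  }

  speckled <- clean * exp(draws$noise) / exp(spec$speckle_sigma^2 / 2)
  bias_field <- if (is.null(spec$bias)) matrix(0, spec$size, spec$size)
  else eval_surface(spec$bias, nrow = spec$size, ncol = spec$size)
  img <- pmin(pmax(speckled + bias_field, 0), 1)
  list(image = as_gray_image(img, rescale_8bit = FALSE),
       class_label = spec$class_label,
       label = as.integer(spec$class_label == "malignant"),
       bias_field = bias_field, mask = mask,
       clean = clean, speckled = speckled)
}

# Random degree-2 surface scaled so the field's peak absolute value over a
# size x size grid equals `strength`; zero surface when strength is 0.
random_bias_surface <- function(strength, size, degree = 2) {
  n_coef <- (degree + 1) * (degree + 2) / 2 - 1
  if (strength <= 0) return(polynomial_surface(rep(0, n_coef), degree))
  coef <- stats::rnorm(n_coef)
  s <- polynomial_surface(coef, degree)
  peak <- max(abs(eval_surface(s, nrow = size, ncol = size)))
  polynomial_surface(coef * strength / peak, degree)
}

#' Generate a seeded train/test phantom dataset
#'
#' Draws per-sample jittered phantom specs (center, axes, intensities,
#' margin irregularity, missing-boundary arcs, bias surfaces scaled to
#' `bias_strength` peak amplitude), renders them, and splits stratified by
#' class. All draws flow from `seed`, so the same arguments reproduce the
#' dataset bit for bit.
#'
#' @param n_benign,n_malignant Class sizes (total `>= 4`).
#' @param test_fraction Fraction held out, in (0, 1). The test size is
#'   `round(test_fraction * n)`, allocated to classes by largest
#'   remainder.
#' @param seed Integer seed.
#' @param bias_strength Peak absolute amplitude of the injected degree-2
#'   bias field. Default 0.15; 0 disables bias.
#' @param size Image side. Default 28.
#' @param speckle_sigma Speckle scale. Default 0.05.
#' @param out_dir If non-`NULL`, write `<id>.png` per image, a
#'   `labels.csv` (columns `filename,label`), and exact bias fields as
#'   32-bit float TIFFs under `truth/`, affinely mapped to `(P + 1) / 2`
#'   so the signed field fits TIFF's \[0, 1\] convention (recover with
#'   `2 * v - 1`).
#' @return A list of class `phantom_dataset` with elements `train` and
#'   `test` (each: `images` list, `labels` 0/1 vector, `ids`,
#'   `bias_fields`, `speckled` bias-free references), plus `specs` and the
#'   generating parameters.
#' @export
make_dataset <- function(n_benign, n_malignant, test_fraction, seed,
                         bias_strength = 0.15, size = 28,
                         speckle_sigma = 0.05, out_dir = NULL) {
  if (n_benign + n_malignant < 4)
    stop("need at least 4 samples in total", call. = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must lie strictly between 0 and 1", call. = FALSE)
  set.seed(seed)
  n <- n_benign + n_malignant
  classes <- rep(c("benign", "malignant"), c(n_benign, n_malignant))
  ids <- sprintf("%s%03d", ifelse(classes == "benign", "b", "m"),
                 stats::ave(seq_len(n), classes, FUN = seq_along))

  specs <- vector("list", n)
  for (i in seq_len(n)) {
    malignant <- classes[i] == "malignant"
    specs[[i]] <- phantom_spec(
      size = size, class_label = classes[i],
      lesion_center = (size + 1) / 2 + stats::runif(2, -2, 2),
      lesion_axes = c(stats::runif(1, 5, 8), stats::runif(1, 3.5, 6)),
      margin_amplitude = if (malignant) stats::runif(1, 0.25, 0.4) else 0,
      margin_lobes = if (malignant) sample(6:10, 1) else 0L,
      mu_lesion = stats::runif(1, 0.27, 0.33),
      mu_background = stats::runif(1, 0.62, 0.68),
      speckle_sigma = speckle_sigma,
      bias = random_bias_surface(bias_strength, size),
      boundary_dropout = if (malignant) stats::runif(1, 0.2, 0.5) else 0,
      seed = sample.int(.Machine$integer.max - 1L, 1))
  }
  rendered <- lapply(specs, render_phantom)

  n_test <- round(test_fraction * n)
  if (n_test < 1 || n_test >= n)
    stop("`test_fraction` leaves an empty split", call. = FALSE)
  quota <- split_quota(c(benign = n_benign, malignant = n_malignant), n_test)
  test_idx <- sort(c(sample(which(classes == "benign"), quota["benign"]),
                     sample(which(classes == "malignant"),
                            quota["malignant"])))
  for (part_idx in list(test_idx, setdiff(seq_len(n), test_idx))) {
    for (cl in c("benign", "malignant"))
      if (sum(classes[part_idx] == cl) < 2)
        stop("each class needs at least 2 samples on both sides of the split",
             call. = FALSE)
  }

  take <- function(idx) list(
    images = lapply(rendered[idx], `[[`, "image"),
    labels = vapply(rendered[idx], `[[`, integer(1), "label"),
    ids = ids[idx],
    bias_fields = lapply(rendered[idx], `[[`, "bias_field"),
    speckled = lapply(rendered[idx], `[[`, "speckled"))
  out <- structure(list(train = take(setdiff(seq_len(n), test_idx)),
                        test = take(test_idx),
                        specs = specs,
                        params = list(n_benign = n_benign,
                                      n_malignant = n_malignant,
                                      test_fraction = test_fraction,
                                      seed = seed,
                                      bias_strength = bias_strength,
                                      size = size,
                                      speckle_sigma = speckle_sigma)),
                   class = "phantom_dataset")
  if (!is.null(out_dir)) write_dataset(out, rendered, ids, classes, out_dir)
  out
}

# Largest-remainder allocation of n_test across classes.
split_quota <- function(class_sizes, n_test) {
  exact <- class_sizes * n_test / sum(class_sizes)
  base <- floor(exact)
  rem <- n_test - sum(base)
  if (rem > 0) {
    order_rem <- order(exact - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  }
  base
}

write_dataset <- function(ds, rendered, ids, classes, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  for (i in seq_along(rendered)) {
    write_gray_image(rendered[[i]]$image,
                     file.path(out_dir, paste0(ids[i], ".png")))
    # bias fields take values in (-1, 1); stored affinely as (P + 1) / 2
    # because TIFF storage outside [0, 1] is undefined in the writer
    write_gray_image((rendered[[i]]$bias_field + 1) / 2,
                     file.path(out_dir, "truth",
                               paste0(ids[i], "_bias.tif")))
  }
  utils::write.csv(data.frame(filename = paste0(ids, ".png"),
                              label = classes),
                   file.path(out_dir, "labels.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(out_dir)
}

#' Flatten a list of images into a sample-by-pixel matrix
#'
#' Column-major flattening; the inverse of `matrix(x, size, size)`.
#'
#' @param images List of equal-size numeric matrices.
#' @return Numeric matrix, one row per image.
#' @export
images_to_matrix <- function(images) {
  do.call(rbind, lapply(images, function(m) as.vector(unclass(m))))
}
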