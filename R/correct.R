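#' Jointly fit region means and a polynomial bias surface
#'
#' Under the additive model `O_i = mu_psi(i) + P(x_i, y_i) + n_i` the
#' observed intensity is a region mean (foreground or background) plus a
#' smooth polynomial field plus noise. Given a bipartition, all parameters
#' are linear, so the cost
#' `eps^2 = (1/Npix) * sum_i (O_i - mu_psi(i) - P_i)^2`
#' is minimized in one linear least-squares solve: the design matrix
#' concatenates the two region-indicator columns with the monomial columns
#' of [build_design_matrix()] over normalized coordinates.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param bipartition A `bipartition` from [fuzzy_bipartition()] (its hard
#'   labels select which mean each pixel gets).
#' @param degree Surface degree, 1 to 4. Default 2.
#' @return A list with `surface` (a `polynomial_surface`), `mu_F`, `mu_B`,
#'   and `epsilon2`, the achieved mean squared residual.
#' @examples
#' img <- cbind(matrix(0.3, 8, 4), matrix(0.7, 8, 4))
#' bp <- fuzzy_bipartition(img)
#' fit_surface(img, bp, degree = 1)$epsilon2
#' @export
fit_surface <- function(image, bipartition, degree = 2) {
  if (degree < 1 || degree > 4)
    stop("`degree` must be between 1 and 4", call. = FALSE)
  img <- unclass(image)
  hard <- bipartition$hard_labels
  if (!any(hard == "F") || !any(hard == "B"))
    stop_degenerate("bipartition has an empty region")

  cc <- pixel_coords(nrow(img), ncol(img))
  coords <- cbind(as.vector(cc$x), as.vector(cc$y))
  X_poly <- build_design_matrix(coords, degree)
  is_f <- as.numeric(as.vector(hard) == "F")
  X <- cbind(muF = is_f, muB = 1 - is_f, X_poly)
  o <- as.vector(img)

  fit <- qr(X, LAPACK = TRUE)
  if (fit$rank < ncol(X)) {
    warning("rank-deficient surface fit; using minimum-norm solution",
            call. = FALSE)
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% o) / sv$d[pos])
    beta <- drop(beta)
  } else {
    beta <- qr.coef(fit, o)
  }
  resid <- o - drop(X %*% beta)
  list(surface = polynomial_surface(beta[-(1:2)], degree),
       mu_F = unname(beta[1]), mu_B = unname(beta[2]),
       epsilon2 = mean(resid^2))
}

#' Correct the intensity inhomogeneity of an ROI image
#'
#' Estimates and removes the bias field by alternating (1) a fuzzy
#' cell-based bipartition of the current corrected estimate, (2) a joint
#' least-squares fit of region means and polynomial surface against the
#' original image under that bipartition, and (3) subtraction of the fitted
#' surface, `corrected = clip(original - P_hat, 0, 1)`. The loop stops when
#' the relative change of the fit cost drops below `tol`, when the cost
#' stops improving, or after `max_outer_iter` rounds; `max_outer_iter = 1`
#' gives the single-pass variant.
#'
#' Degenerate inputs (constant image, or a bipartition that empties one
#' region) do not fail: the image is returned unchanged with a zero surface,
#' `converged = FALSE` and a warning.
#'
#' @param image Numeric matrix in \[0, 1\], at least 8x8.
#' @param degree Surface degree, 1-4. Default 2.
#' @param cell_size Bipartition cell size. Default 4.
#' @param max_outer_iter Maximum bipartition/fit rounds. Default 10.
#' @param tol Relative tolerance on the cost change. Default 1e-4.
#' @return A list of class `correction_result`: `corrected` (same
#'   dimensions, clipped to \[0, 1\]), `surface`, `bias` (the surface
#'   evaluated on the pixel grid), `bipartition`, `mu_F`, `mu_B`,
#'   `epsilon2`, `iterations`, `converged`.
#' @examples
#' img <- cbind(matrix(0.3, 12, 6), matrix(0.7, 12, 6))
#' res <- correct_image(img, degree = 1)
#' res$converged
#' @export
correct_image <- function(image, degree = 2, cell_size = 4,
                          max_outer_iter = 10, tol = 1e-4) {
  img <- unclass(image)
  assert_correctable(img)
  nr <- nrow(img); nc <- ncol(img)
  zero_surface <- polynomial_surface(rep(0, (degree + 1) * (degree + 2) / 2 - 1),
                                     degree)
  fallback <- function(msg) {
    warning("correction fallback (", msg, "); returning input unchanged",
            call. = FALSE)
    structure(list(corrected = img, surface = zero_surface,
                   bias = matrix(0, nr, nc), bipartition = NULL,
                   mu_F = NA_real_, mu_B = NA_real_,
                   epsilon2 = NA_real_, iterations = 0L, converged = FALSE),
              class = "correction_result")
  }

  # Alternation is not guaranteed monotone in the fit cost (the
  # bipartition step optimizes memberships, not epsilon2), so the loop
  # runs its course and the state with the smallest epsilon2 is kept.
  corrected <- img
  best <- NULL
  eps_prev <- Inf
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_outer_iter)) {
    bp <- tryCatch(fuzzy_bipartition(corrected, cell_size = cell_size),
                   sonodae_degenerate_bipartition = function(e) e)
    if (inherits(bp, "condition")) {
      if (is.null(best)) return(fallback(conditionMessage(bp)))
      break  # keep the best fit found so far
    }
    fit <- fit_surface(img, bp, degree = degree)
    iters <- it
    bias <- eval_surface(fit$surface, nrow = nr, ncol = nc)
    corrected <- pmin(pmax(img - bias, 0), 1)
    if (is.null(best) || fit$epsilon2 <= best$fit$epsilon2)
      best <- list(fit = fit, bp = bp, bias = bias, corrected = corrected)
    if (is.finite(eps_prev) &&
        abs(eps_prev - fit$epsilon2) < tol * max(fit$epsilon2, 1e-300)) {
      converged <- TRUE
      break
    }
    eps_prev <- fit$epsilon2
  }
  if (is.null(best)) return(fallback("no successful fit"))
  structure(list(corrected = best$corrected, surface = best$fit$surface,
                 bias = best$bias, bipartition = best$bp,
                 mu_F = best$fit$mu_F, mu_B = best$fit$mu_B,
                 epsilon2 = best$fit$epsilon2, iterations = iters,
                 converged = converged),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf(
    "<correction_result %dx%d: eps2=%.3e, %d outer iters, converged=%s>\n",
    nrow(x$corrected), ncol(x$corrected), x$epsilon2, x$iterations,
    x$converged))
  invisible(x)
}

#' Coefficient of variation of the background region
#'
#' Diagnostic used to quantify how much a correction flattened the
#' background: sd/mean of the intensities at background-labeled pixels.
#'
#' @param image Numeric matrix.
#' @param bipartition A `bipartition`; its `"B"`-labeled pixels define the
#'   background.
#' @return A single number (`NA` if the background is empty).
#' @export
background_cv <- function(image, bipartition) {
  v <- unclass(image)[bipartition$hard_labels == "B"]
  if (!length(v)) return(NA_real_)
  stats::sd(v) / mean(v)
}
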