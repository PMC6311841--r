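#' Fuzzy cell-based foreground/background bipartition
#'
#' Splits an ROI into a hypoechoic foreground (the lesion) and a brighter
#' background, the two "homogeneous areas" whose means anchor the additive
#' inhomogeneity model. The image is tiled into `cell_size x cell_size`
#' cells (edge cells may be smaller), each cell is summarized by its mean
#' intensity, and two-cluster fuzzy c-means is run on the cell means. The
#' cell-level pooling is the spatially constrained part of the procedure:
#' cluster centers are estimated from speckle-averaged cell means, so they
#' are robust to pixel noise. Each pixel's final fuzzy membership is then
#' computed from its own intensity relative to those two centers (same FCM
#' membership formula), so that cells straddling the lesion margin do not
#' force a whole block of pixels to one side — block-correlated label
#' errors at the margin would otherwise leak into the polynomial surface
#' fit. The cluster with the lower center is labeled foreground, since
#' lesions are hypoechoic.
#'
#' A spatial constraint resolves the ambiguity between "dark because
#' lesion" and "dark because of the bias field": in a lesion-centered ROI
#' the foreground must be one compact region at the image center, whereas
#' bias-induced dark patches hug corners or edges. Foreground membership
#' is therefore kept only on the connected component of candidate
#' foreground pixels that contains the ROI center (falling back to the
#' largest component when the center pixel is background); everything else
#' is assigned to the background, whose smooth darkening the polynomial
#' surface is left to explain. The pixel stage alternates membership,
#' constraint and center re-estimation to a fixed point, so that the
#' foreground center settles on the actual lesion statistics even when
#' the lesion occupies a small minority of the image.
#'
#' FCM is deterministic here: centers are initialized at the 25th and 75th
#' percentiles of the cell means, memberships use the standard inverse
#' squared-distance update with fuzzifier `m`, and iteration stops when the
#' largest membership change drops below `tol`.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param cell_size Cell side length in pixels, `>= 2`. Default 4, suited to
#'   28x28 ROIs; use 8 for larger images.
#' @param fuzzifier FCM fuzzifier `m > 1`. Default 2.
#' @param max_iter Maximum FCM iterations. Default 100.
#' @param tol Convergence tolerance on the membership change. Default 1e-5.
#' @return A list of class `bipartition` with elements `membership`
#'   (pixel-level foreground membership in \[0, 1\]), `hard_labels`
#'   (character matrix over `"F"`/`"B"`, foreground iff membership >= 0.5),
#'   `mu_F`, `mu_B` (membership-weighted pixel means, `mu_F < mu_B`),
#'   `centers` (cell-level FCM centers) and `iterations`.
#' @examples
#' img <- cbind(matrix(0.2, 8, 4), matrix(0.8, 8, 4))
#' bp <- fuzzy_bipartition(img)
#' bp$mu_F; bp$mu_B
#' @export
fuzzy_bipartition <- function(image, cell_size = 4, fuzzifier = 2,
                              max_iter = 100, tol = 1e-5) {
  if (cell_size < 2) stop("`cell_size` must be >= 2", call. = FALSE)
  if (fuzzifier <= 1) stop("`fuzzifier` must be > 1", call. = FALSE)
  img <- unclass(image)
  nr <- nrow(img); nc <- ncol(img)

  row_cell <- (seq_len(nr) - 1) %/% cell_size
  col_cell <- (seq_len(nc) - 1) %/% cell_size
  cell_id <- outer(row_cell, col_cell,
                   function(r, c) r * (max(col_cell) + 1) + c)
  cell_means <- as.vector(tapply(as.vector(img), as.vector(cell_id), mean))

  if (diff(range(img)) < 1e-12 || diff(range(cell_means)) < 1e-12)
    stop_degenerate("image has (near-)constant intensity; cannot bipartition")

  centers <- stats::quantile(cell_means, c(0.25, 0.75), names = FALSE)
  if (diff(centers) < 1e-12)
    centers <- range(cell_means)  # heavy ties at the quartiles
  if (diff(centers) < 1e-12)
    stop_degenerate("cell means do not separate into two clusters")

  expo <- 2 / (fuzzifier - 1)
  u <- fcm_membership(cell_means, centers, expo)
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    um_f <- u^fuzzifier
    um_b <- (1 - u)^fuzzifier
    centers <- c(sum(um_f * cell_means) / sum(um_f),
                 sum(um_b * cell_means) / sum(um_b))
    u_new <- fcm_membership(cell_means, centers, expo)
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) break
  }
  # enforce foreground = lower-center cluster
  if (centers[1] > centers[2]) {
    centers <- rev(centers)
    u <- 1 - u
  }

  # pixel-level constrained FCM: alternate (membership from centers) ->
  # (keep only the central connected foreground blob) -> (re-estimate
  # centers from the constrained memberships) to a fixed point. The
  # re-estimation step matters when the cohort is imbalanced (a small
  # lesion among many background cells drags the cell-level foreground
  # center upward); without it the drifted center admits bias-darkened
  # background into the foreground.
  memb <- NULL
  for (px_it in seq_len(20)) {
    memb <- matrix(fcm_membership(as.vector(img), centers, expo), nr, nc)
    cand <- memb >= 0.5
    if (any(cand) && !all(cand)) {
      labs <- EBImage::bwlabel(cand)
      center_lab <- labs[round(nr / 2), round(nc / 2)]
      if (center_lab == 0) {
        sizes <- tabulate(labs[labs > 0])
        center_lab <- which.max(sizes)
      }
      memb[labs != center_lab] <- 0
    }
    um_f <- memb^fuzzifier
    um_b <- (1 - memb)^fuzzifier
    if (sum(um_f) < 1e-12 || sum(um_b) < 1e-12) break
    new_centers <- c(sum(um_f * img) / sum(um_f),
                     sum(um_b * img) / sum(um_b))
    moved <- max(abs(new_centers - centers))
    centers <- sort(new_centers)
    if (moved < 1e-6) break
  }
  hard <- ifelse(memb >= 0.5, "F", "B")
  if (!any(hard == "F") || !any(hard == "B"))
    stop_degenerate("hard assignment left one region empty")

  mu_F <- sum(memb * img) / sum(memb)
  mu_B <- sum((1 - memb) * img) / sum(1 - memb)
  structure(list(membership = memb, hard_labels = hard,
                 mu_F = mu_F, mu_B = mu_B,
                 centers = centers, iterations = iter),
            class = "bipartition")
}

# Foreground membership for each point given centers (fg, bg).
fcm_membership <- function(x, centers, expo) {
  d_f <- abs(x - centers[1])
  d_b <- abs(x - centers[2])
  u <- 1 / (1 + (d_f / d_b)^expo)
  u[d_f < .Machine$double.eps & d_b < .Machine$double.eps] <- 0.5
  u[d_f < .Machine$double.eps & d_b >= .Machine$double.eps] <- 1
  u[d_b < .Machine$double.eps & d_f >= .Machine$double.eps] <- 0
  u
}

stop_degenerate <- function(msg) {
  cond <- structure(class = c("sonodae_degenerate_bipartition", "error",
                              "condition"),
                    list(message = msg, call = NULL))
  stop(cond)
}

#' @export
print.bipartition <- function(x, ...) {
  cat(sprintf(
    "<bipartition %dx%d: mu_F=%.4f mu_B=%.4f (%d F pixels), %d FCM iters>\n",
    nrow(x$membership), ncol(x$membership), x$mu_F, x$mu_B,
    sum(x$hard_labels == "F"), x$iterations))
  invisible(x)
}
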