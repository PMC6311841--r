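#' Design matrix of bivariate monomials
#'
#' One row per coordinate pair, one column per monomial `x^j * y^k` with
#' `1 <= j + k <= degree`, in graded lexicographic order: total degree
#' ascending, and within each total degree the power of `x` descending
#' (`x, y, x^2, xy, y^2, x^3, ...`). The constant term is deliberately
#' excluded: in the additive image model the constant offset is carried by
#' the region means, and a constant column would make the joint fit
#' unidentifiable.
#'
#' @param coords Two-column matrix (or coercible) of normalized `(x, y)`
#'   points, each coordinate in \[-1, 1\].
#' @param degree Nonnegative integer; `degree = 0` yields a matrix with
#'   zero columns.
#' @return Numeric matrix, `nrow(coords)` rows and
#'   `(degree + 1) * (degree + 2) / 2 - 1` columns, with column names such
#'   as `"x1y0"`.
#' @examples
#' build_design_matrix(cbind(0.5, -0.5), degree = 2)
#' @export
build_design_matrix <- function(coords, degree) {
  if (length(degree) != 1 || is.na(degree) || degree < 0 ||
      degree != as.integer(degree))
    stop("`degree` must be a single nonnegative integer", call. = FALSE)
  coords <- as.matrix(coords)
  if (ncol(coords) != 2)
    stop("`coords` must have two columns (x, y)", call. = FALSE)
  exps <- monomial_exponents(degree)
  out <- matrix(0, nrow(coords), nrow(exps))
  for (m in seq_len(nrow(exps)))
    out[, m] <- coords[, 1]^exps[m, 1] * coords[, 2]^exps[m, 2]
  if (ncol(out) > 0)
    colnames(out) <- paste0("x", exps[, 1], "y", exps[, 2])
  out
}

# (j, k) exponent pairs in graded lexicographic order, constant excluded.
monomial_exponents <- function(degree) {
  if (degree == 0)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("j", "k"))))
  pairs <- do.call(rbind, lapply(seq_len(degree), function(d)
    cbind(j = d:0, k = 0:d)))
  pairs
}

#' Construct a polynomial bias surface
#'
#' A bias field over the image domain, represented as a bivariate polynomial
#' in the normalized \[-1, 1\]^2 pixel coordinates of [pixel_coords()]. It
#' has no constant term, so the field is mean-free by construction up to the
#' grid asymmetry of the even monomials.
#'
#' @param coefficients Numeric vector, one value per monomial in the order
#'   of [build_design_matrix()]; length must be
#'   `(degree + 1) * (degree + 2) / 2 - 1`.
#' @param degree Polynomial degree `N >= 0`.
#' @return An object of class `polynomial_surface`.
#' @export
polynomial_surface <- function(coefficients, degree) {
  n_expect <- (degree + 1) * (degree + 2) / 2 - 1
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != n_expect)
    stop(sprintf("degree %d surface needs %d coefficients, got %d",
                 degree, n_expect, length(coefficients)), call. = FALSE)
  if (!all(is.finite(coefficients)))
    stop("surface coefficients must be finite", call. = FALSE)
  exps <- monomial_exponents(degree)
  names(coefficients) <- if (nrow(exps)) paste0("x", exps[, 1], "y", exps[, 2])
  structure(list(degree = as.integer(degree), coefficients = coefficients),
            class = "polynomial_surface")
}

#' Evaluate a polynomial surface
#'
#' @param surface A `polynomial_surface`.
#' @param coords Two-column matrix of normalized coordinates, or `NULL` to
#'   evaluate over a full image grid given `nrow`/`ncol`.
#' @param nrow,ncol Grid dimensions when `coords` is `NULL`; the result is
#'   then returned as an `nrow x ncol` matrix.
#' @return Numeric vector (per coordinate row) or matrix (grid evaluation).
#' @export
eval_surface <- function(surface, coords = NULL, nrow = NULL, ncol = NULL) {
  stopifnot(inherits(surface, "polynomial_surface"))
  grid <- is.null(coords)
  if (grid) {
    cc <- pixel_coords(nrow, ncol)
    coords <- cbind(as.vector(cc$x), as.vector(cc$y))
  }
  if (surface$degree == 0 || length(surface$coefficients) == 0) {
    v <- rep(0, nrow(as.matrix(coords)))
  } else {
    v <- drop(build_design_matrix(coords, surface$degree) %*%
                surface$coefficients)
  }
  if (grid) matrix(v, nrow, ncol) else v
}

#' @export
print.polynomial_surface <- function(x, ...) {
  cat(sprintf("<polynomial_surface degree %d>\n", x$degree))
  if (length(x$coefficients)) print(signif(x$coefficients, 4))
  invisible(x)
}
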