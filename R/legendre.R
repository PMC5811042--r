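#' Legendre polynomial basis over an age interval
#'
#' Defines the basis used to parameterise age trajectories: ages in months on
#' \code{[t_min, t_max]} are mapped linearly onto \code{[-1, 1]} and the
#' Legendre polynomials \eqn{P_0 \ldots P_n} are evaluated there.  Under the
#' default normalised convention each polynomial is scaled by
#' \eqn{\sqrt{(2k+1)/2}} so the basis is orthonormal on \code{[-1, 1]}, the
#' convention used throughout random-regression quantitative genetics; the
#' raw convention (\eqn{P_k(1) = 1}) is available for cross-checks.
#'
#' @param order Polynomial order \eqn{n \ge 0} (basis has \code{order + 1}
#'   functions).  Orders above 5 are rejected: they invite overfitting on
#'   longitudinal data with a handful of records per individual.
#' @param t_min,t_max Age bounds in months, \code{t_max > t_min}.
#' @param normalized Logical; use the orthonormal scaling (default) or raw
#'   Legendre polynomials.
#' @return An object of class \code{legendre_basis}.
#' @examples
#' b <- legendre_basis(2, 0, 60)
#' basis_row(0, b)   # phi(0 months): first element sqrt(1/2)
#' @export
legendre_basis <- function(order, t_min, t_max, normalized = TRUE) {
  stopifnot(length(order) == 1L, length(t_min) == 1L, length(t_max) == 1L)
  order <- as.integer(order)
  if (is.na(order) || order < 0L)
    stop("'order' must be a non-negative integer")
  if (order > 5L)
    stop("'order' must be <= 5: higher orders overfit sparse longitudinal data")
  if (!is.finite(t_min) || !is.finite(t_max) || t_max <= t_min)
    stop("age bounds must satisfy t_max > t_min")
  structure(
    list(order = order, t_min = as.numeric(t_min), t_max = as.numeric(t_max),
         normalized = isTRUE(normalized)),
    class = "legendre_basis"
  )
}

#' @export
print.legendre_basis <- function(x, ...) {
  cat(sprintf("Legendre basis: order %d on [%g, %g] months (%s convention)\n",
              x$order, x$t_min, x$t_max,
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

#' Map an age in months onto the standardized interval [-1, 1]
#'
#' \code{x = -1 + 2 (t - t_min) / (t_max - t_min)}.  Out-of-bounds ages are an
#' error unless \code{clamp = TRUE}, in which case they are pinned to the
#' nearest bound (an explicit opt-in for plotting/extrapolation).
#'
#' @param t Age(s) in months.
#' @param basis A \code{\link{legendre_basis}}.
#' @param clamp Clamp out-of-range ages instead of erroring.
#' @return Numeric vector in \code{[-1, 1]}.
#' @export
standardize_age <- function(t, basis, clamp = FALSE) {
  stopifnot(inherits(basis, "legendre_basis"))
  t <- as.numeric(t)
  bad <- !is.na(t) & (t < basis$t_min | t > basis$t_max)
  if (any(bad)) {
    if (clamp) {
      t <- pmin(pmax(t, basis$t_min), basis$t_max)
    } else {
      stop(sprintf("age(s) out of basis bounds [%g, %g]: %s",
                   basis$t_min, basis$t_max,
                   paste(utils::head(t[bad], 5L), collapse = ", ")))
    }
  }
  -1 + 2 * (t - basis$t_min) / (basis$t_max - basis$t_min)
}

## Raw Legendre polynomials by the three-term recurrence
## (k+1) P_{k+1}(x) = (2k+1) x P_k(x) - k P_{k-1}(x),
## evaluated columnwise for a vector of x.
legendre_raw <- function(x, order) {
  m <- matrix(0, length(x), order + 1L)
  m[, 1L] <- 1
  if (order >= 1L) m[, 2L] <- x
  if (order >= 2L) {
    for (k in 1L:(order - 1L)) {
      m[, k + 2L] <- ((2 * k + 1) * x * m[, k + 1L] - k * m[, k]) / (k + 1)
    }
  }
  m
}

#' Evaluate the basis at given ages
#'
#' Returns the matrix \eqn{\Phi} with one row per age and columns
#' \eqn{\phi_0(x), \ldots, \phi_n(x)}; \code{basis_row} is the single-age
#' convenience returning a plain vector.  These are the row vectors that
#' multiply the fixed and random regression coefficients in the trajectory
#' model and the vector \eqn{p} of the additive-variance quadratic form
#' \eqn{V_A(t) = p K p'}.
#'
#' @param t Age(s) in months.
#' @param basis A \code{\link{legendre_basis}}.
#' @param clamp Passed to \code{\link{standardize_age}}.
#' @return \code{basis_matrix}: numeric matrix \code{length(t) x (order+1)};
#'   \code{basis_row}: numeric vector of length \code{order + 1}.
#' @export
basis_matrix <- function(t, basis, clamp = FALSE) {
  stopifnot(inherits(basis, "legendre_basis"))
  x <- standardize_age(t, basis, clamp = clamp)
  m <- legendre_raw(x, basis$order)
  if (basis$normalized) {
    k <- 0:basis$order
    m <- sweep(m, 2L, sqrt((2 * k + 1) / 2), `*`)
  }
  dimnames(m) <- list(NULL, paste0("phi", 0:basis$order))
  m
}

#' @rdname basis_matrix
#' @export
basis_row <- function(t, basis, clamp = FALSE) {
  stopifnot(length(t) == 1L)
  drop(basis_matrix(t, basis, clamp = clamp))
}

#' Default evaluation grid: integer months spanning the basis bounds
#'
#' @param basis A \code{\link{legendre_basis}}.
#' @param by Grid step in months (default 1).
#' @return Numeric vector of ages.
#' @export
age_grid <- function(basis, by = 1) {
  stopifnot(inherits(basis, "legendre_basis"))
  seq(basis$t_min, basis$t_max, by = by)
}
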