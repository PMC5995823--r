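#' Gaussian-broadened density of states of a conformer ensemble
#'
#' Each conformer at relative energy E contributes a normalized Gaussian
#' phi(x) = 1/(alpha * sqrt(pi)) * exp(-(x - E)^2 / alpha^2), so the curve
#' integrates to the number of conformers.
#'
#' @param energies_rel Relative energies in kcal/mol (>= 0); may be empty.
#' @param alpha Broadening parameter in kcal/mol (default 0.24).
#' @param grid Energy grid in kcal/mol.  Default: 0 to
#'   `max(4, max(energies))` at 0.01 steps, padded by 5 * alpha on each side
#'   so the normalization check holds.
#' @return A list of class `dos_curve` with `grid`, `density`, `alpha`,
#'   `n_conformers`.
#' @export
dos_curve <- function(energies_rel, alpha = 0.24, grid = NULL) {
  if (!is.numeric(alpha) || alpha <= 0) stop("'alpha' must be positive")
  energies_rel <- as.numeric(energies_rel)
  if (anyNA(energies_rel) || any(energies_rel < 0))
    stop("relative energies must be finite and >= 0")
  if (is.null(grid)) {
    hi <- if (length(energies_rel)) max(4, max(energies_rel)) else 4
    grid <- seq(-5 * alpha, hi + 5 * alpha, by = 0.01)
  }
  dens <- rep(0, length(grid))
  for (e in energies_rel)
    dens <- dens + exp(-((grid - e) / alpha)^2) / (alpha * sqrt(pi))
  structure(list(grid = grid, density = dens, alpha = alpha,
                 n_conformers = length(energies_rel)),
            class = "dos_curve")
}

#' @export
print.dos_curve <- function(x, ...) {
  cat("density of states:", x$n_conformers, "conformers, alpha =", x$alpha,
      "kcal/mol\n")
  cat(sprintf("  grid %g..%g kcal/mol (%d points), integral %.4f\n",
              min(x$grid), max(x$grid), length(x$grid),
              pracma::trapz(x$grid, x$density)))
  invisible(x)
}

#' @export
plot.dos_curve <- function(x, ...) {
  graphics::plot(x$grid, x$density, type = "l",
                 xlab = "relative energy (kcal/mol)",
                 ylab = "density of states (1/kcal/mol)", ...)
  invisible(x)
}

#' Overlap between two density-of-states curves
#'
#' Quantifies the agreement of two DOS curves on a common grid as
#' integral(min(a, b)) / integral(max(a, b)) by the trapezoidal rule:
#' 1 for identical curves, 0 for disjoint supports.
#'
#' @param a,b `dos_curve` objects on the same grid.
#' @return Overlap in \[0, 1\].
#' @export
compare_dos <- function(a, b) {
  stopifnot(inherits(a, "dos_curve"), inherits(b, "dos_curve"))
  if (length(a$grid) != length(b$grid) ||
      max(abs(a$grid - b$grid)) > 1e-9)
    stop("curves must share the same energy grid")
  hi <- pracma::trapz(a$grid, pmax(a$density, b$density))
  if (hi == 0) return(1)  # two empty curves
  pracma::trapz(a$grid, pmin(a$density, b$density)) / hi
}
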