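#' Published trial-structure counts for the three search methods
#'
#' Trial-structure counts for peptide backbones of n = 3..10 residues under
#' the exhaustive systematic search (`N_sys`), the path-matrix method
#' (`N_PM`) and the random-forest assisted divide-and-conquer search
#' (`N_RF`).  `N_sys` and `N_PM` grow analytically; `N_RF` is measured for
#' n <= 6 and estimated beyond by assuming ~50 additional low-energy
#' fragment conformers per added residue.
#'
#' @return Data frame of class `cost_table` with columns `n`, `N_sys`,
#'   `N_PM`, `N_RF`.
#' @export
builtin_table2 <- function() {
  out <- data.frame(
    n = 3:10,
    N_sys = c(3456, 41472, 4.98e5, 5.97e6, 7.17e7, 8.60e8, 1.03e10, 1.24e11),
    N_PM = c(240, 1130, 5310, 2.49e4, 1.17e5, 5.50e5, 2.58e6, 1.21e7),
    N_RF = c(1838, 4096, 5438, 6649, 7318, 8540, 9613, 11341))
  class(out) <- c("cost_table", "data.frame")
  out
}

#' Geometric extrapolation of trial-structure counts
#'
#' Fits a per-residue growth ratio from the first two known points,
#' r = (c2/c1)^(1/(n2 - n1)), and extrapolates
#' count(n) = count(n0) * r^(n - n0).
#'
#' @param known Data frame or matrix with columns `n` and `count` (at least
#'   two rows; ordered by n).
#' @param n_target Length to extrapolate to (>= smallest known n).
#' @return The extrapolated count (exact at the anchor; compare published
#'   values at 3 significant figures).
#' @examples
#' known <- data.frame(n = c(3, 4), count = c(3456, 41472))
#' signif(geometric_extrapolate(known, 10), 3)  # 1.24e11
#' @export
geometric_extrapolate <- function(known, n_target) {
  known <- as.data.frame(known)
  if (!all(c("n", "count") %in% names(known)))
    names(known)[1:2] <- c("n", "count")
  if (nrow(known) < 2L) stop("need at least two known points")
  known <- known[order(known$n), ]
  if (n_target < known$n[1])
    stop("'n_target' must not precede the first known point")
  r <- (known$count[2] / known$count[1])^(1 / (known$n[2] - known$n[1]))
  known$count[1] * r^(n_target - known$n[1])
}

#' Per-residue growth factor of a trial-count column
#'
#' Geometric mean of the successive-n count ratios over a range of n,
#' reported to 2 significant figures.
#'
#' @param column Data frame or matrix with columns `n` and `count`.
#' @param n_range Optional `c(min, max)` restriction of n.
#' @return Growth factor per added residue (2 significant figures).
#' @examples
#' t2 <- builtin_table2()
#' growth_factor(data.frame(n = t2$n, count = t2$N_PM))       # 4.7
#' growth_factor(data.frame(n = t2$n, count = t2$N_RF), c(4, 10))  # 1.2
#' @export
growth_factor <- function(column, n_range = NULL) {
  column <- as.data.frame(column)
  if (!all(c("n", "count") %in% names(column)))
    names(column)[1:2] <- c("n", "count")
  column <- column[order(column$n), ]
  if (!is.null(n_range))
    column <- column[column$n >= n_range[1] & column$n <= n_range[2], ]
  if (nrow(column) < 2L) stop("need at least two points in the range")
  k <- nrow(column)
  gm <- (column$count[k] / column$count[1])^(1 / (column$n[k] - column$n[1]))
  signif(gm, 2)
}
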