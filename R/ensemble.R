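#' Construct a phi-psi conformer ensemble
#'
#' An ensemble holds the backbone dihedral description of every conformer of
#' one peptide: for an n-residue peptide each conformer is a string of n - 1
#' phi-psi units (unit i belongs to residue i + 1), plus a relative energy in
#' kcal/mol.  A "low-energy" conformer is one within `energy_window` kcal/mol
#' of the ensemble's global minimum (default 10).
#'
#' @param peptide One-letter amino-acid sequence (upper case, n >= 2).
#' @param phi,psi Numeric matrices, one row per conformer and one column per
#'   unit (n - 1 columns), angles in degrees.
#' @param energy Numeric vector of energies in kcal/mol, one per conformer,
#'   or `NULL`/all-`NA` when energies are unknown.  Energies are re-based so
#'   the minimum is 0.
#' @param id Optional character vector of conformer ids.
#' @param energy_window Width of the low-energy window in kcal/mol.
#' @return An object of class `phipsi_ensemble`.
#' @seealso [low_energy()], [read_ensemble()], [sample_ensemble()]
#' @export
phipsi_ensemble <- function(peptide, phi, psi, energy = NULL, id = NULL,
                            energy_window = 10) {
  stopifnot(is.character(peptide), length(peptide) == 1L, nchar(peptide) >= 2L)
  peptide <- toupper(peptide)
  phi <- rbind(phi); psi <- rbind(psi)
  phi <- matrix(wrap_angle(phi), nrow(phi), ncol(phi))
  psi <- matrix(wrap_angle(psi), nrow(psi), ncol(psi))
  n_units <- nchar(peptide) - 1L
  if (ncol(phi) != n_units || ncol(psi) != n_units)
    stop("expected ", n_units, " units for peptide ", peptide)
  if (nrow(phi) != nrow(psi)) stop("'phi' and 'psi' must have equal rows")
  nc <- nrow(phi)
  if (nc < 1L) stop("ensemble must contain at least one conformer")
  if (is.null(energy)) energy <- rep(NA_real_, nc)
  if (length(energy) != nc) stop("'energy' length must match conformer count")
  if (!all(is.na(energy))) {
    if (anyNA(energy)) stop("energies must be all present or all absent")
    energy <- energy - min(energy)
  }
  if (is.null(id)) id <- sprintf("conf%04d", seq_len(nc))
  if (anyDuplicated(id)) stop("conformer ids must be unique")
  structure(list(peptide = peptide, phi = phi, psi = psi,
                 energy = as.numeric(energy), id = as.character(id),
                 energy_window = energy_window),
            class = "phipsi_ensemble")
}

#' @export
print.phipsi_ensemble <- function(x, ...) {
  nle <- n_conformers(low_energy(x))
  cat("phi-psi ensemble of", x$peptide, "(", nchar(x$peptide), "residues,",
      ncol(x$phi), "units )\n")
  cat("  conformers:", n_conformers(x),
      if (all(is.na(x$energy))) "(no energies)"
      else sprintf("(%d within %.3g kcal/mol of the minimum)",
                   nle, x$energy_window), "\n")
  invisible(x)
}

#' Number of conformers in an ensemble
#' @param x A `phipsi_ensemble`.
#' @return Integer count.
#' @export
n_conformers <- function(x) {
  stopifnot(inherits(x, "phipsi_ensemble"))
  nrow(x$phi)
}

#' Number of phi-psi units per conformer
#' @param x A `phipsi_ensemble`.
#' @return Integer count (n residues - 1).
#' @export
n_units <- function(x) {
  stopifnot(inherits(x, "phipsi_ensemble"))
  ncol(x$phi)
}

#' Subset an ensemble by conformer index
#' @param x A `phipsi_ensemble`.
#' @param i Conformer indices (integer or logical).
#' @param ... Ignored.
#' @return A `phipsi_ensemble` with the selected conformers; energies are not
#'   re-based, so relative energies keep their meaning under subsetting.
#' @export
`[.phipsi_ensemble` <- function(x, i, ...) {
  out <- x
  out$phi <- x$phi[i, , drop = FALSE]
  out$psi <- x$psi[i, , drop = FALSE]
  out$energy <- x$energy[i]
  out$id <- x$id[i]
  if (nrow(out$phi) < 1L) stop("subset removes every conformer")
  out
}

#' Low-energy view of an ensemble
#'
#' Returns the conformers whose relative energy lies within the ensemble's
#' energy window of the global minimum.  When no energies are recorded every
#' conformer is treated as low-energy.
#'
#' @param x A `phipsi_ensemble`.
#' @param window Optional override of the window in kcal/mol.
#' @return A `phipsi_ensemble` containing only the low-energy conformers.
#' @export
low_energy <- function(x, window = NULL) {
  stopifnot(inherits(x, "phipsi_ensemble"))
  if (is.null(window)) window <- x$energy_window
  if (all(is.na(x$energy))) return(x)
  x[x$energy <= window]
}

#' Conformer dihedral table
#'
#' @param x A `phipsi_ensemble`.
#' @param row.names,optional,... Passed through to [base::as.data.frame()]
#'   conventions (unused).
#' @return Data frame with columns `id`, `phi1`, `psi1`, ..., `energy`.
#' @export
as.data.frame.phipsi_ensemble <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  k <- n_units(x)
  out <- data.frame(id = x$id, stringsAsFactors = FALSE)
  for (j in seq_len(k)) {
    out[[paste0("phi", j)]] <- x$phi[, j]
    out[[paste0("psi", j)]] <- x$psi[, j]
  }
  out$energy <- x$energy
  out
}

#' Per-unit angle samples from one or more ensembles
#'
#' Collects, for every phi-psi unit of every ensemble, the (phi, psi)
#' observations across the ensemble's low-energy conformers.  The result is
#' the raw material of the pairwise error-rate analysis: each element is a
#' two-column matrix named by its canonical unit label (e.g. `"gfgg2"`).
#'
#' @param ensembles A `phipsi_ensemble` or list of them.
#' @return Named list of two-column matrices (`phi`, `psi`).
#' @export
unit_samples <- function(ensembles) {
  if (inherits(ensembles, "phipsi_ensemble")) ensembles <- list(ensembles)
  out <- list()
  for (e in ensembles) {
    stopifnot(inherits(e, "phipsi_ensemble"))
    le <- low_energy(e)
    for (j in seq_len(n_units(e))) {
      lab <- format_unit_label(e$peptide, j)
      if (!is.null(out[[lab]]))
        stop("duplicate unit label across ensembles: ", lab)
      out[[lab]] <- cbind(phi = le$phi[, j], psi = le$psi[, j])
    }
  }
  out
}
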