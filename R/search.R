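#' Minimal fragment lengths for a divide-and-conquer splice
#'
#' For a target of n residues split into an N-side fragment of n1 residues
#' and a C-side fragment of n2 residues, the minimal lengths are
#' n1 = int((n - 1)/2) + 2 and n2 = int(n/2) + 1.
#'
#' @param n Target peptide length (n >= 3).
#' @return Named integer vector `c(n1 = ..., n2 = ...)`.
#' @examples
#' minimal_fragment_lengths(5)  # c(n1 = 4, n2 = 3)
#' @export
minimal_fragment_lengths <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("'n' must be an integer >= 3")
  c(n1 = (n - 1L) %/% 2L + 2L, n2 = n %/% 2L + 1L)
}

#' Plan the splice of two fragment ensembles onto a target peptide
#'
#' The N-side fragment (n1 residues) supplies target units 1 .. n1 - 2 from
#' its own units 1 .. n1 - 2.  The C-side fragment (n2 residues) supplies
#' target units n1 - 1 .. n - 1; its unit k maps to target unit
#' k + (n - n2), so at the junction residue shared by both fragments the
#' C-fragment's phi-psi value is authoritative and the N-fragment's is
#' discarded.  The junction pair screened by the grammar is target units
#' (n1 - 2, n1 - 1).
#'
#' @param n Target length (>= 3).
#' @param n1,n2 Fragment lengths; defaults from
#'   [minimal_fragment_lengths()].  Larger fragments (up to n) may be used.
#' @return A list of class `splice_plan` with the unit-index mapping:
#'   `n_source`/`n_target` and `c_source`/`c_target` index vectors and
#'   `junction = c(n1 - 2, n1 - 1)`.
#' @export
make_splice_plan <- function(n, n1 = NULL, n2 = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) stop("'n' must be an integer >= 3")
  if (is.null(n1) || is.null(n2)) {
    mf <- minimal_fragment_lengths(n)
    if (is.null(n1)) n1 <- mf[["n1"]]
    if (is.null(n2)) n2 <- mf[["n2"]]
  }
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (n1 < 3L) stop("'n1' must be >= 3 (the N fragment supplies n1 - 2 units)")
  if (n2 < 2L) stop("'n2' must be >= 2")
  if (n1 > n || n2 > n) stop("fragments longer than the target are not used")
  if (n1 + n2 < n + 2L)
    stop("fragments too short to cover the target with a junction overlap: ",
         "need n1 + n2 >= n + 2")
  offset <- n - n2
  n_target <- seq_len(n1 - 2L)
  c_target <- (n1 - 1L):(n - 1L)
  structure(list(n = n, n1 = n1, n2 = n2,
                 n_source = n_target, n_target = n_target,
                 c_source = c_target - offset, c_target = c_target,
                 c_offset = offset,
                 junction = c(n1 - 2L, n1 - 1L)),
            class = "splice_plan")
}

#' @export
print.splice_plan <- function(x, ...) {
  cat("splice plan: target n =", x$n, " from fragments n1 =", x$n1,
      ", n2 =", x$n2, "\n")
  cat("  N fragment units", paste(range(x$n_source), collapse = "-"),
      "-> target units", paste(range(x$n_target), collapse = "-"), "\n")
  cat("  C fragment units", paste(range(x$c_source), collapse = "-"),
      "-> target units", paste(range(x$c_target), collapse = "-"), "\n")
  cat("  junction screened: target units (", x$junction[1], ",",
      x$junction[2], ")\n")
  invisible(x)
}

#' Generate trial structures by splicing two fragment ensembles
#'
#' Forms every combination of the low-energy conformers of the N-side and
#' C-side ensembles and assembles each combination's target phi-psi string
#' according to the plan.  Trials are ordered lexicographically by
#' (N-parent id, C-parent id).
#'
#' @param ensN,ensC `phipsi_ensemble`s of the two fragments; their lengths
#'   must match `plan$n1` and `plan$n2`.
#' @param plan A [make_splice_plan()].
#' @param target Optional target sequence (defaults to the concatenation
#'   implied by the fragments is not assumed; used only for bookkeeping).
#' @return A list of class `trial_set`: `phi`/`psi` matrices (one row per
#'   trial, n - 1 columns), `parents` data frame, `plan`, `screened`
#'   status vector (`"not-yet"`, `"accept"`, `"reject"`).
#' @export
generate_trials <- function(ensN, ensC, plan, target = NULL) {
  stopifnot(inherits(plan, "splice_plan"),
            inherits(ensN, "phipsi_ensemble"),
            inherits(ensC, "phipsi_ensemble"))
  if (nchar(ensN$peptide) != plan$n1)
    stop("N fragment has ", nchar(ensN$peptide), " residues, plan needs ",
         plan$n1)
  if (nchar(ensC$peptide) != plan$n2)
    stop("C fragment has ", nchar(ensC$peptide), " residues, plan needs ",
         plan$n2)
  leN <- low_energy(ensN); leC <- low_energy(ensC)
  iN <- order(leN$id); iC <- order(leC$id)
  grid <- expand.grid(c = iC, n = iN)[, c("n", "c")]  # n-major, lexicographic
  k <- plan$n - 1L
  nt <- nrow(grid)
  phi <- matrix(NA_real_, nt, k); psi <- matrix(NA_real_, nt, k)
  phi[, plan$n_target] <- leN$phi[grid$n, plan$n_source, drop = FALSE]
  psi[, plan$n_target] <- leN$psi[grid$n, plan$n_source, drop = FALSE]
  phi[, plan$c_target] <- leC$phi[grid$c, plan$c_source, drop = FALSE]
  psi[, plan$c_target] <- leC$psi[grid$c, plan$c_source, drop = FALSE]
  structure(list(phi = phi, psi = psi,
                 parents = data.frame(n_id = leN$id[grid$n],
                                      c_id = leC$id[grid$c],
                                      stringsAsFactors = FALSE),
                 plan = plan, target = target,
                 screened = rep("not-yet", nt)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat("trial set:", nrow(x$phi), "trial structures of", x$plan$n - 1L,
      "units\n")
  st <- table(x$screened)
  cat("  screening status:",
      paste(names(st), st, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Screen trial structures at the splice junction
#'
#' Applies the grammar classifier to each trial's junction combination
#' (the phi-psi values of target units n1 - 2 and n1 - 1) and keeps exactly
#' the accepted trials, preserving order.
#'
#' @param trials A [generate_trials()] result.
#' @param model A trained [train_grammar()] model for the matching junction
#'   context.
#' @param plan Optional plan override (defaults to `trials$plan`).
#' @return A `trial_set` containing the surviving trials (all marked
#'   `"accept"`).
#' @export
screen_trials <- function(trials, model, plan = NULL) {
  stopifnot(inherits(trials, "trial_set"))
  if (is.null(plan)) plan <- trials$plan
  j <- plan$junction
  combos <- cbind(trials$phi[, j[1]], trials$psi[, j[1]],
                  trials$phi[, j[2]], trials$psi[, j[2]])
  verdict <- screen_combo(model, combos)
  keep <- verdict == "accept"
  out <- trials
  out$phi <- trials$phi[keep, , drop = FALSE]
  out$psi <- trials$psi[keep, , drop = FALSE]
  out$parents <- trials$parents[keep, , drop = FALSE]
  out$screened <- rep("accept", sum(keep))
  out
}

#' Remove near-duplicate trial structures
#'
#' Greedy first-keeper deduplication: a trial is dropped when every one of
#' its angles is within `tol` degrees (circular) of an already-kept trial.
#'
#' @param trials A `trial_set`.
#' @param tol Per-angle tolerance in degrees (default 3).
#' @return The deduplicated `trial_set`.
#' @export
dedupe_trials <- function(trials, tol = 3) {
  stopifnot(inherits(trials, "trial_set"), tol >= 0)
  nt <- nrow(trials$phi)
  keep <- logical(nt)
  kept_idx <- integer(0)
  for (i in seq_len(nt)) {
    dup <- FALSE
    for (j in kept_idx) {
      if (all(circular_diff(trials$phi[i, ], trials$phi[j, ]) <= tol) &&
          all(circular_diff(trials$psi[i, ], trials$psi[j, ]) <= tol)) {
        dup <- TRUE; break
      }
    }
    if (!dup) { keep[i] <- TRUE; kept_idx <- c(kept_idx, i) }
  }
  out <- trials
  out$phi <- trials$phi[keep, , drop = FALSE]
  out$psi <- trials$psi[keep, , drop = FALSE]
  out$parents <- trials$parents[keep, , drop = FALSE]
  out$screened <- trials$screened[keep]
  out
}

#' Convert surviving trials to an ensemble
#'
#' Packages a trial set as a [phipsi_ensemble()] of the target sequence so
#' it can be written out (dihedral CSV or rebuilt multi-model PDB) for
#' external optimisation.
#'
#' @param trials A `trial_set`.
#' @param target Target sequence (n residues).
#' @return A `phipsi_ensemble` without energies.
#' @export
trials_as_ensemble <- function(trials, target) {
  stopifnot(inherits(trials, "trial_set"))
  if (nchar(target) != trials$plan$n)
    stop("'target' must have ", trials$plan$n, " residues")
  phipsi_ensemble(target, trials$phi, trials$psi,
                  id = paste(trials$parents$n_id, trials$parents$c_id,
                             sep = "x"))
}

#' Substitute a fragment ensemble by a class-equivalent one
#'
#' When the conformers of a required fragment are unknown, an available
#' ensemble may stand in for it provided every one of its units falls in
#' the same equivalence class as the corresponding unit of the requested
#' fragment (side chains are conceptually replaced: rebuilt structures use
#' the target's residue identities).
#'
#' @param target_fragment Sequence of the fragment whose conformers are
#'   needed.
#' @param classes A [cluster_units()] result covering the candidate units
#'   (and the target units, when they were part of the learning set).
#' @param available List of candidate `phipsi_ensemble`s.
#' @param target_classes Optional integer vector giving the required class
#'   of each target unit, for targets outside the learning set.  Defaults
#'   to looking the target's own unit labels up in `classes`.
#' @return The first class-compatible ensemble, with attribute
#'   `"substitution"` documenting the replacement.
#' @export
substitute_fragment <- function(target_fragment, classes, available,
                                target_classes = NULL) {
  stopifnot(inherits(classes, "unit_classes"))
  target_fragment <- toupper(target_fragment)
  if (length(available) == 0L) stop("no candidate ensembles available")
  k <- nchar(target_fragment) - 1L
  if (is.null(target_classes)) {
    labs <- format_unit_label(target_fragment, seq_len(k))
    if (!all(labs %in% names(classes$classes)))
      stop("target units ", paste(setdiff(labs, names(classes$classes)),
                                  collapse = ", "),
           " are not in 'classes'; supply 'target_classes'")
    target_classes <- unname(classes$classes[labs])
  }
  if (length(target_classes) != k)
    stop("'target_classes' must give one class per target unit")
  near_misses <- character(0)
  for (e in available) {
    stopifnot(inherits(e, "phipsi_ensemble"))
    if (n_units(e) != k) {
      near_misses <- c(near_misses,
                       paste0(e$peptide, " (", n_units(e), " units)"))
      next
    }
    labs <- format_unit_label(e$peptide, seq_len(k))
    if (!all(labs %in% names(classes$classes))) {
      near_misses <- c(near_misses, paste0(e$peptide, " (unclassified units)"))
      next
    }
    cand <- unname(classes$classes[labs])
    if (all(cand == target_classes)) {
      attr(e, "substitution") <- paste0(e$peptide, " standing in for ",
                                        target_fragment)
      return(e)
    }
    near_misses <- c(near_misses,
                     paste0(e$peptide, " (classes ",
                            paste(cand, collapse = ","), " vs required ",
                            paste(target_classes, collapse = ","), ")"))
  }
  stop("no class-compatible ensemble for ", target_fragment,
       "; candidates: ", paste(near_misses, collapse = "; "))
}
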