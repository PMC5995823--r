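#' Canonical Ramachandran basins for synthetic ensembles
#'
#' Five well-separated basins at textbook Ramachandran positions:
#' right-handed alpha helix, beta sheet, polyproline II, left-handed alpha
#' and the gamma/bridge region, each with an isotropic angular spread.
#'
#' @param sd Angular standard deviation in degrees (default 10).
#' @return Data frame with columns `name`, `phi`, `psi`, `sd`.
#' @export
default_basins <- function(sd = 10) {
  data.frame(name = c("alphaR", "beta", "PPII", "alphaL", "gamma"),
             phi = c(-63, -120, -75, 57, -85),
             psi = c(-43, 130, 150, 47, 70),
             sd = sd, stringsAsFactors = FALSE)
}

#' Adjacency rule for synthetic ensembles
#'
#' @param allowed Two-column matrix or data frame of basin-name pairs that
#'   adjacent units (i, i + 1) may jointly occupy.
#' @param margin Gap in degrees separating the allowed combination regions
#'   from disallowed combinations (used by the benchmark generator).
#' @return A list of class `grammar_spec`.
#' @export
grammar_spec <- function(allowed, margin = 30) {
  allowed <- as.matrix(allowed)
  if (nrow(allowed) < 1L || ncol(allowed) != 2L)
    stop("'allowed' must be a non-empty two-column matrix of basin names")
  structure(list(allowed = allowed, margin = margin), class = "grammar_spec")
}

## internal: default adjacency rule used by the generators
default_grammar <- function() {
  grammar_spec(rbind(c("alphaR", "alphaR"),
                     c("beta", "beta"),
                     c("beta", "PPII"),
                     c("PPII", "alphaR"),
                     c("gamma", "beta")))
}

## internal: truncated normal noise (+- trunc_sd standard deviations)
truncnorm_deg <- function(n, sd, trunc_sd = 3) {
  lim <- stats::pnorm(c(-trunc_sd, trunc_sd))
  stats::qnorm(stats::runif(n, lim[1], lim[2])) * sd
}

#' Generate a synthetic conformer ensemble with planted basin structure
#'
#' Emulates the phi-psi statistics of a low-energy conformer ensemble:
#' every unit draws a Ramachandran basin according to its per-unit basin
#' weights, adjacent units are restricted to the allowed basin pairs of the
#' grammar, and angles are the basin mean plus wrapped Gaussian noise
#' truncated at +-3 sd (keeping planted basins disjoint so ground truth is
#' unambiguous).  Energies are a placeholder: the first conformer sits at 0
#' and the rest are uniform on (0, 10].
#'
#' @param peptide Target sequence (labels only; basins do not depend on
#'   residue identity beyond `class_weights`).
#' @param n_conf Number of conformers (>= 1).
#' @param class_weights Matrix of basin weights, one row per unit and one
#'   column per basin (rows are renormalized); a single vector is recycled
#'   across units.  Default: uniform over all basins.
#' @param basins [default_basins()]-style data frame.
#' @param grammar A [grammar_spec()]; the default allows the basin pairs
#'   (alphaR, alphaR), (beta, beta), (beta, PPII), (PPII, alphaR) and
#'   (gamma, beta).
#' @param seed Integer seed; the same seed reproduces the ensemble exactly.
#' @return A [phipsi_ensemble()] with attribute `"basin_path"` (matrix of
#'   planted basin names, for oracle checks).
#' @export
sample_ensemble <- function(peptide, n_conf, class_weights = NULL,
                            basins = default_basins(),
                            grammar = default_grammar(), seed = 1L) {
  stopifnot(n_conf >= 1L)
  peptide <- toupper(peptide)
  k <- nchar(peptide) - 1L
  nb <- nrow(basins)
  if (is.null(class_weights)) class_weights <- rep(1, nb)
  if (is.null(dim(class_weights)))
    class_weights <- matrix(class_weights, k, nb, byrow = TRUE)
  if (nrow(class_weights) != k || ncol(class_weights) != nb)
    stop("'class_weights' must be ", k, " x ", nb)
  adj <- matrix(FALSE, nb, nb, dimnames = list(basins$name, basins$name))
  for (r in seq_len(nrow(grammar$allowed)))
    adj[grammar$allowed[r, 1], grammar$allowed[r, 2]] <- TRUE
  # viable[[j]]: basins usable at unit j so that the chain can be completed
  viable <- vector("list", k)
  viable[[k]] <- which(class_weights[k, ] > 0)
  if (k > 1L) for (j in (k - 1L):1L) {
    viable[[j]] <- which(class_weights[j, ] > 0 &
                           apply(adj[, viable[[j + 1L]], drop = FALSE], 1, any))
  }
  if (any(vapply(viable, length, 1L) == 0L))
    stop("inconsistent grammar: some unit has no allowed continuation")
  with_seed(seed, {
    path <- matrix(NA_integer_, n_conf, k)
    for (ci in seq_len(n_conf)) {
      w <- class_weights[1, viable[[1]]]
      path[ci, 1] <- viable[[1]][sample.int(length(viable[[1]]), 1,
                                            prob = w)]
      if (k > 1L) for (j in 2:k) {
        ok <- viable[[j]][adj[path[ci, j - 1L], viable[[j]]]]
        if (length(ok) == 0L)
          stop("inconsistent grammar: basin ", basins$name[path[ci, j - 1L]],
               " has no allowed continuation at unit ", j)
        w <- class_weights[j, ok]
        path[ci, j] <- ok[sample.int(length(ok), 1, prob = w)]
      }
    }
    phi <- matrix(wrap_angle(basins$phi[path] +
                               truncnorm_deg(n_conf * k, basins$sd[path])),
                  n_conf, k)
    psi <- matrix(wrap_angle(basins$psi[path] +
                               truncnorm_deg(n_conf * k, basins$sd[path])),
                  n_conf, k)
    energy <- c(0, stats::runif(n_conf - 1L, 0, 10))
    ens <- phipsi_ensemble(peptide, phi, psi, energy = energy)
    attr(ens, "basin_path") <- matrix(basins$name[path], n_conf, k)
    ens
  })
}

#' Synthetic benchmark of labeled adjacent-unit combinations
#'
#' Positives are drawn inside the allowed basin pairs (basin mean plus
#' Gaussian noise truncated at 3 sd, so each allowed region extends 3 sd
#' from its centre per angle).  Negatives emulate the unfavorable
#' combinations a junction screen actually faces: cross products of
#' individually plausible unit values in pairings that never co-occur.
#' They are drawn from the disallowed basin pairs (same per-unit noise) and
#' kept only when they sit at least `margin` degrees outside the edge of
#' every allowed region, i.e. at per-angle circular distance
#' >= 3 sd + margin from every allowed pair centre (distance of a
#' combination to a centre = the maximum over its four angle offsets).
#'
#' @param n_pos,n_neg Numbers of favorable / unfavorable combinations.
#' @param margin Gap in degrees between the allowed-region edge and the
#'   nearest unfavorable combination (> 0).
#' @param seed Integer seed.
#' @param basins,grammar Basin table and allowed-pair rule (defaults as in
#'   [sample_ensemble()]).
#' @param sd Noise standard deviation for positives (default 10, truncated
#'   at 3 sd).
#' @return Data frame with columns `phi_i, psi_i, phi_j, psi_j`, `label`
#'   (1 favorable / 0 unfavorable) and `source`.
#' @export
make_grammar_benchmark <- function(n_pos, n_neg, margin = 30, seed = 1L,
                                   basins = default_basins(),
                                   grammar = default_grammar(), sd = 10) {
  if (margin <= 0) stop("'margin' must be positive")
  al <- grammar$allowed
  pair_centres <- function(pairs)
    cbind(basins$phi[match(pairs[, 1], basins$name)],
          basins$psi[match(pairs[, 1], basins$name)],
          basins$phi[match(pairs[, 2], basins$name)],
          basins$psi[match(pairs[, 2], basins$name)])
  centres <- pair_centres(al)
  if (anyNA(centres)) stop("allowed pairs refer to unknown basins")
  all_pairs <- expand.grid(basins$name, basins$name,
                           stringsAsFactors = FALSE)
  dis <- all_pairs[!(paste(all_pairs[, 1], all_pairs[, 2]) %in%
                       paste(al[, 1], al[, 2])), , drop = FALSE]
  if (nrow(dis) == 0L) stop("every basin pair is allowed: no negatives exist")
  dis_centres <- pair_centres(as.matrix(dis))
  with_seed(seed, {
    pick <- sample.int(nrow(centres), n_pos, replace = TRUE)
    pos <- centres[pick, , drop = FALSE] +
      matrix(truncnorm_deg(4L * n_pos, sd), n_pos, 4)
    neg <- matrix(NA_real_, 0, 4)
    attempts <- 0L
    while (nrow(neg) < n_neg) {
      attempts <- attempts + 1L
      if (attempts > 2000L)
        stop("margin ", margin,
             " leaves too little room to place unfavorable combinations")
      dpick <- sample.int(nrow(dis_centres), n_neg, replace = TRUE)
      cand <- dis_centres[dpick, , drop = FALSE] +
        matrix(truncnorm_deg(4L * n_neg, sd), n_neg, 4)
      ok <- vapply(seq_len(nrow(cand)), function(r) {
        dmin <- min(vapply(seq_len(nrow(centres)), function(cc)
          max(circular_diff(cand[r, ], centres[cc, ])), 0))
        dmin >= 3 * sd + margin
      }, TRUE)
      neg <- rbind(neg, cand[ok, , drop = FALSE])
    }
    neg <- neg[seq_len(n_neg), , drop = FALSE]
    out <- data.frame(rbind(wrap_angle(pos), wrap_angle(neg)))
    names(out) <- c("phi_i", "psi_i", "phi_j", "psi_j")
    out$label <- rep(c(1L, 0L), c(n_pos, n_neg))
    out$source <- rep(c("allowed-pair", "disallowed-pair"), c(n_pos, n_neg))
    out
  })
}
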