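#' Enumerate labeled adjacent-unit combinations from ensembles
#'
#' For each ensemble, the distinct observed values of unit i and of unit
#' j = i + 1 among the low-energy conformers are combined in a combinatorial
#' cross product.  A combination (phi_i, psi_i, phi_j, psi_j) is labeled 1
#' (favorable) if some low-energy conformer of the same ensemble has all
#' four angles within `noise_deg` degrees (circular, per angle) of it, else
#' 0 (unfavorable).  Combinations taken directly from an observed conformer
#' therefore always carry label 1.
#'
#' @param ensembles A `phipsi_ensemble` or list of them.
#' @param pair Integer pair `c(i, i + 1)` of adjacent unit indices.
#' @param noise_deg Per-angle matching tolerance in degrees (default 3).
#' @return Data frame with columns `phi_i, psi_i, phi_j, psi_j`, `label`
#'   (integer 0/1) and `source` (peptide of the contributing ensemble).
#' @export
enumerate_pair_dataset <- function(ensembles, pair, noise_deg = 3) {
  if (inherits(ensembles, "phipsi_ensemble")) ensembles <- list(ensembles)
  pair <- as.integer(pair)
  if (length(pair) != 2L || pair[2] != pair[1] + 1L)
    stop("'pair' must be two adjacent unit indices c(i, i + 1)")
  out <- list()
  for (e in ensembles) {
    stopifnot(inherits(e, "phipsi_ensemble"))
    if (pair[2] > n_units(e))
      stop("ensemble ", e$peptide, " has no unit ", pair[2])
    le <- low_energy(e)
    obs <- cbind(le$phi[, pair[1]], le$psi[, pair[1]],
                 le$phi[, pair[2]], le$psi[, pair[2]])
    ui <- unique(obs[, 1:2, drop = FALSE])
    uj <- unique(obs[, 3:4, drop = FALSE])
    grid <- cbind(ui[rep(seq_len(nrow(ui)), each = nrow(uj)), , drop = FALSE],
                  uj[rep(seq_len(nrow(uj)), times = nrow(ui)), , drop = FALSE])
    lab <- vapply(seq_len(nrow(grid)), function(r) {
      any(vapply(seq_len(nrow(obs)), function(o)
        all(circular_diff(grid[r, ], obs[o, ]) <= noise_deg), TRUE))
    }, TRUE)
    out[[length(out) + 1L]] <- data.frame(
      phi_i = grid[, 1], psi_i = grid[, 2],
      phi_j = grid[, 3], psi_j = grid[, 4],
      label = as.integer(lab), source = e$peptide,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Stratified random split of a labeled combination dataset
#'
#' @param data Data frame with a `label` column (0/1).
#' @param frac Training fraction in (0, 1), default 0.6.
#' @param seed Integer seed; the same seed always yields the same split.
#' @return List with elements `train` and `holdout`; per-label training
#'   counts are `round(frac * n_label)`, so sizes are within 1 of
#'   `frac * N` per class.
#' @export
split_dataset <- function(data, frac = 0.6, seed = 1L) {
  stopifnot(is.data.frame(data), "label" %in% names(data))
  if (!(frac > 0 && frac < 1)) stop("'frac' must lie strictly in (0, 1)")
  if (length(unique(data$label)) < 2L)
    stop("both labels must be present to split")
  with_seed(seed, {
    idx <- unlist(lapply(split(seq_len(nrow(data)), data$label),
                         function(ix) sample(ix, round(frac * length(ix)))))
  })
  idx <- sort(idx)
  list(train = data[idx, , drop = FALSE],
       holdout = data[-idx, , drop = FALSE])
}

#' Train the adjacent-unit combination ("grammar") classifier
#'
#' Fits a random forest mapping an adjacent-unit combination
#' (phi_i, psi_i, phi_j, psi_j) to favorable (1) / unfavorable (0).
#' Combinatorial negatives typically outnumber observed positives, so
#' classes are weighted inversely to their frequencies.  The in-sample
#' error is the training-set misclassification rate of the fitted forest
#' (the out-of-bag rate is kept alongside as `oob_error`); when a holdout
#' set is supplied the out-of-sample error is its plain misclassification
#' rate.
#'
#' @param train Data frame from [enumerate_pair_dataset()] /
#'   [split_dataset()] (columns `phi_i, psi_i, phi_j, psi_j, label`).
#' @param rf An [rf_control()]; the grammar defaults to the `"full"` angle
#'   encoding (sin, cos and wrapped degrees per angle).
#' @param holdout Optional holdout data frame of the same shape.
#' @return An object of class `grammar_model` with components `fit` (the
#'   forest), `rf` (settings), `in_sample_error`, `oob_error`,
#'   `out_of_sample_error` (`NA` without a holdout), `n_train`.
#' @seealso [screen_combo()], [screen_trials()], [stability_check()]
#' @export
train_grammar <- function(train, rf = rf_control(encode = "full"),
                          holdout = NULL) {
  stopifnot(is.data.frame(train),
            all(c("phi_i", "psi_i", "phi_j", "psi_j", "label")
                %in% names(train)))
  y <- factor(train$label, levels = c(0, 1))
  if (any(table(y) == 0L))
    stop("training set must contain both favorable and unfavorable combos")
  x <- encode_angles(as.matrix(train[c("phi_i", "psi_i", "phi_j", "psi_j")]),
                     rf$encode)
  wt <- as.numeric(1 / table(y)); wt <- wt / sum(wt)
  fit <- with_seed(rf$seed,
                   randomForest::randomForest(x, y, ntree = rf$ntree,
                                              classwt = wt))
  model <- structure(list(fit = fit, rf = rf,
                          in_sample_error =
                            mean(stats::predict(fit, x) != y),
                          oob_error = unname(fit$err.rate[rf$ntree, "OOB"]),
                          out_of_sample_error = NA_real_,
                          n_train = nrow(train)),
                     class = "grammar_model")
  if (!is.null(holdout)) {
    pred <- screen_combo(model,
                         holdout[c("phi_i", "psi_i", "phi_j", "psi_j")])
    model$out_of_sample_error <-
      mean((pred == "accept") != (holdout$label == 1))
    model$n_holdout <- nrow(holdout)
  }
  model
}

#' @export
print.grammar_model <- function(x, ...) {
  cat("phi-psi combination grammar (random forest,", x$rf$ntree, "trees)\n")
  cat(sprintf("  trained on %d combinations; in-sample error %.4f (OOB %.4f)\n",
              x$n_train, x$in_sample_error, x$oob_error))
  if (!is.na(x$out_of_sample_error))
    cat(sprintf("  out-of-sample error %.4f on %d held-out combinations\n",
                x$out_of_sample_error, x$n_holdout))
  invisible(x)
}

#' @export
summary.grammar_model <- function(object, ...) {
  print(object)
  tab <- table(object$fit$y)
  cat("  training class counts: unfavorable =", tab[["0"]],
      ", favorable =", tab[["1"]], "\n")
  cat("  settings: encode =", object$rf$encode, ", seed =", object$rf$seed,
      "\n")
  invisible(object)
}

#' Predict whether combinations are favorable
#'
#' @param model A trained [train_grammar()] model.
#' @param combo Numeric vector of length 4 (`phi_i, psi_i, phi_j, psi_j`) or
#'   a 4-column matrix / data frame of combinations.
#' @return Character vector `"accept"` (predicted favorable) / `"reject"`.
#' @export
screen_combo <- function(model, combo) {
  if (!inherits(model, "grammar_model") || is.null(model$fit))
    stop("'model' must be a trained grammar_model")
  if (is.null(dim(combo))) combo <- matrix(as.numeric(combo), ncol = 4,
                                           byrow = TRUE)
  combo <- as.matrix(combo)
  if (ncol(combo) != 4) stop("combinations must have 4 angle columns")
  colnames(combo) <- c("phi_i", "psi_i", "phi_j", "psi_j")
  x <- encode_angles(combo, model$rf$encode)
  pred <- stats::predict(model$fit, x)
  ifelse(pred == "1", "accept", "reject")
}

#' @export
predict.grammar_model <- function(object, newdata, ...) {
  screen_combo(object, newdata)
}

#' Split-fraction stability of the grammar classifier
#'
#' Retrains the grammar at several training fractions and reports the
#' error rates, mirroring the check that the learned combination rule does
#' not depend on the train/holdout division.
#'
#' @param data Labeled combination data frame.
#' @param fracs Numeric vector of training fractions in (0, 1).
#' @param rf An [rf_control()].
#' @param seed Base seed; fraction f uses seed `seed + rank(f)`.
#' @param threshold Error level the report checks against (default 0.02).
#' @return Data frame with one row per fraction: `frac`, `seed`,
#'   `in_sample_error`, `out_of_sample_error`, `below_threshold`.
#' @export
stability_check <- function(data, fracs = c(0.5, 0.6, 0.7),
                            rf = rf_control(encode = "full"), seed = 1L,
                            threshold = 0.02) {
  if (length(fracs) == 0L)
    return(data.frame(frac = numeric(), seed = integer(),
                      in_sample_error = numeric(),
                      out_of_sample_error = numeric(),
                      below_threshold = logical()))
  rows <- lapply(seq_along(fracs), function(i) {
    s <- seed + i
    sp <- split_dataset(data, fracs[i], seed = s)
    m <- train_grammar(sp$train, rf = rf, holdout = sp$holdout)
    data.frame(frac = fracs[i], seed = s,
               in_sample_error = m$in_sample_error,
               out_of_sample_error = m$out_of_sample_error,
               below_threshold = m$in_sample_error < threshold &
                 m$out_of_sample_error < threshold)
  })
  do.call(rbind, rows)
}
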