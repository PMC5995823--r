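#' Random-forest settings
#'
#' Shared configuration for the random-forest estimators in the package.
#'
#' @param ntree Number of trees (default 500).
#' @param encode `"sincos"` (default) encodes each angle as (sin, cos) so
#'   the classifier respects the periodicity of the circle; `"degrees"`
#'   feeds raw wrapped degrees; `"full"` supplies both (used by the grammar
#'   classifier, where axis-aligned angle splits matter).
#' @param seed Integer seed used for down-sampling and forest growth;
#'   recorded in outputs for reproducibility.
#' @return A list of class `rf_control`.
#' @export
rf_control <- function(ntree = 500, encode = c("sincos", "degrees", "full"),
                       seed = 1L) {
  structure(list(ntree = as.integer(ntree), encode = match.arg(encode),
                 seed = as.integer(seed)),
            class = "rf_control")
}

#' Pairwise random-forest error rate between two phi-psi unit samples
#'
#' Trains a random forest to separate the (phi, psi) observations of one
#' unit from those of another and returns its out-of-bag misclassification
#' rate.  Class sizes are balanced beforehand by down-sampling the larger
#' sample to the smaller (seeded).  An error rate near 0.5 (chance level for
#' balanced classes) means the two distributions are indistinguishable; an
#' error near 0 means they are well separated.
#'
#' @param a,b Two-column matrices of (phi, psi) observations in degrees,
#'   as produced by [unit_samples()].
#' @param rf An [rf_control()].
#' @return Out-of-bag error rate in \[0, 1\].
#' @export
pairwise_error_rate <- function(a, b, rf = rf_control()) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) < 2L || nrow(b) < 2L)
    stop("each unit sample needs at least 2 observations")
  with_seed(rf$seed, {
    n <- min(nrow(a), nrow(b))
    if (nrow(a) > n) a <- a[sample(nrow(a), n), , drop = FALSE]
    if (nrow(b) > n) b <- b[sample(nrow(b), n), , drop = FALSE]
    x <- encode_angles(rbind(a, b), rf$encode)
    y <- factor(rep(c("a", "b"), each = n))
    fit <- randomForest::randomForest(x, y, ntree = rf$ntree)
    unname(fit$err.rate[rf$ntree, "OOB"])
  })
}

## internal constructor for classed error-rate matrices
error_rate_matrix_obj <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  structure(m, class = c("error_rate_matrix", "matrix"))
}

#' Pairwise error-rate matrix over a set of unit samples
#'
#' Computes [pairwise_error_rate()] for every unordered pair of unit
#' samples.  The result is symmetric by construction with an undefined
#' (`NA`) diagonal.
#'
#' @param samples Named list of two-column (phi, psi) matrices, e.g. from
#'   [unit_samples()].
#' @param rf An [rf_control()].
#' @return An `error_rate_matrix` (symmetric, labels as dimnames).
#' @export
error_rate_matrix <- function(samples, rf = rf_control()) {
  if (length(samples) < 2L) stop("need at least 2 unit samples")
  labs <- names(samples)
  if (is.null(labs) || anyDuplicated(labs) || any(!nzchar(labs)))
    stop("samples must carry unique non-empty labels")
  p <- length(samples)
  m <- matrix(NA_real_, p, p, dimnames = list(labs, labs))
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    e <- pairwise_error_rate(samples[[i]], samples[[j]], rf)
    m[i, j] <- m[j, i] <- e
  }
  error_rate_matrix_obj(m)
}

#' @export
print.error_rate_matrix <- function(x, ...) {
  cat("pairwise RF error-rate matrix over", nrow(x), "phi-psi units\n")
  print(round(unclass(x), 2), na.print = "-")
  invisible(x)
}

## internal: error rate -> dissimilarity
error_to_dissimilarity <- function(m, transform = c("one_minus", "proximity"),
                                   fun = NULL) {
  if (!is.null(fun)) d <- fun(m)
  else {
    transform <- match.arg(transform)
    d <- switch(transform,
                one_minus = 1 - m,
                # RF proximity convention: chance-level error 0.5 means
                # identical distributions, d = sqrt(1 - 2e), clamped for the
                # few printed rates above chance
                proximity = sqrt(pmax(1 - 2 * m, 0)))
  }
  diag(d) <- 0
  if (any(d < 0, na.rm = TRUE)) stop("transform produced negative distances")
  d
}

#' Classical MDS embedding of an error-rate matrix
#'
#' Maps error rates to dissimilarities (monotone decreasing transform, by
#' default d = 1 - e with a zero diagonal), then applies classical
#' (Torgerson) scaling: double-centering of -d^2/2 and eigendecomposition.
#' Eigenvalues are reported normalized by the largest; coordinates are the
#' top-2 principal axes.
#'
#' @param m An [error_rate_matrix()] (or plain symmetric matrix).
#' @param transform `"one_minus"` (d = 1 - e, default) or `"proximity"`
#'   (d = sqrt(1 - 2e), the random-forest proximity convention under which
#'   chance-level error means identity).
#' @param fun Optional function overriding `transform`; must map the error
#'   matrix to a dissimilarity matrix.
#' @param k Number of embedding dimensions to keep (default 2).
#' @return A list of class `mds_embedding` with elements `eig` (all
#'   normalized eigenvalues, non-increasing, first = 1), `points`
#'   (k-column coordinate matrix), `transform`, and `degenerate` (flag set
#'   when the dissimilarities carry no usable spread).
#' @export
mds_embed <- function(m, transform = c("one_minus", "proximity"), fun = NULL,
                      k = 2) {
  m <- unclass(as.matrix(m))
  if (!isTRUE(all.equal(m, t(m)))) stop("error-rate matrix must be symmetric")
  d <- error_to_dissimilarity(m, transform, fun)
  degenerate <- stats::sd(d[upper.tri(d)]) < 1e-12
  if (degenerate)
    warning("all dissimilarities equal: embedding is degenerate")
  fit <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
  ev <- fit$eig
  if (ev[1] <= 0) stop("no positive eigenvalue: embedding undefined")
  pts <- fit$points
  if (ncol(pts) < k)   # cmdscale drops axes with ~zero eigenvalue
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  rownames(pts) <- rownames(m)
  structure(list(eig = ev / ev[1], points = pts,
                 transform = if (is.null(fun)) match.arg(transform)
                             else "custom",
                 degenerate = degenerate),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat("classical MDS embedding (", nrow(x$points), "units, transform:",
      x$transform, ")\n")
  cat("  leading normalized eigenvalues:",
      paste(round(utils::head(x$eig, 5), 2), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.mds_embedding <- function(x, ...) {
  graphics::plot(x$points[, 1], x$points[, 2], type = "n",
                 xlab = "MDS axis 1", ylab = "MDS axis 2", ...)
  graphics::text(x$points[, 1], x$points[, 2], labels = rownames(x$points))
  invisible(x)
}

#' Group phi-psi units into equivalence classes
#'
#' Agglomerative (average-linkage) clustering of the 2D MDS coordinates.
#' When `k` is not given it is chosen by mean silhouette width over
#' k = 2..6, taking the smallest k whose mean silhouette is within `sil_tol`
#' of the maximum (a parsimony rule: silhouette differences below ~0.02 are
#' noise-level, and the coarser partition is preferred).
#'
#' @param emb An [mds_embed()] result.
#' @param k Number of classes, or `NULL` for silhouette selection.
#' @param sil_tol Silhouette tolerance of the parsimony rule (default 0.02).
#' @return A list of class `unit_classes`: `classes` (named integer vector),
#'   `k`, `silhouette` (profile over candidate k, when selected).
#' @export
cluster_units <- function(emb, k = NULL, sil_tol = 0.02) {
  stopifnot(inherits(emb, "mds_embedding"))
  pts <- emb$points
  p <- nrow(pts)
  if (p < 3L) stop("need at least 3 labels to cluster")
  if (!is.null(k) && k > p) stop("k exceeds the number of labels")
  dm <- stats::dist(pts)
  if (max(dm) < 1e-12) stop("all points identical: clustering is degenerate")
  hc <- stats::hclust(dm, method = "average")
  sil <- NULL
  if (is.null(k)) {
    ks <- 2:min(6, p - 1L)
    sil <- vapply(ks, function(kk)
      mean(cluster::silhouette(stats::cutree(hc, kk), dm)[, 3]), 0)
    names(sil) <- ks
    k <- ks[which(sil >= max(sil) - sil_tol)[1]]
  }
  cl <- stats::cutree(hc, k)
  structure(list(classes = cl, k = k, silhouette = sil),
            class = "unit_classes")
}

#' @export
print.unit_classes <- function(x, ...) {
  cat("phi-psi unit classes (k =", x$k, ")\n")
  for (g in sort(unique(x$classes)))
    cat("  class", g, ":", paste(names(x$classes)[x$classes == g],
                                 collapse = ", "), "\n")
  invisible(x)
}

#' Units equivalent to a given unit
#'
#' @param classes A [cluster_units()] result.
#' @param label Unit label, e.g. `"gfgg1"`.
#' @return Character vector of the other members of `label`'s class.
#' @export
equivalent_units <- function(classes, label) {
  stopifnot(inherits(classes, "unit_classes"))
  if (!label %in% names(classes$classes)) stop("unknown unit label: ", label)
  g <- classes$classes[[label]]
  setdiff(names(classes$classes)[classes$classes == g], label)
}
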