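test_that("pairwise error rate separates distant basins and saturates at
           chance for identical distributions", {
  rf <- rf_control(ntree = 300, seed = 9)
  far_a <- basin_points(200, c(-60, -45), seed = 1)
  far_b <- basin_points(200, c(140, 135), seed = 2)   # ~200 deg away
  expect_lt(pairwise_error_rate(far_a, far_b, rf), 0.05)
  same_a <- basin_points(200, c(-60, -45), seed = 3)
  same_b <- basin_points(200, c(-60, -45), seed = 4)
  expect_lt(abs(pairwise_error_rate(same_a, same_b, rf) - 0.5), 0.1)
  expect_error(pairwise_error_rate(far_a[1, , drop = FALSE], far_b),
               "at least 2")
})

test_that("pairwise error rate is symmetric within Monte-Carlo noise", {
  rf <- rf_control(ntree = 300, seed = 21)
  a <- basin_points(200, c(-63, -43), seed = 5)
  b <- basin_points(200, c(-85, 70), seed = 6)
  expect_lt(abs(pairwise_error_rate(a, b, rf) -
                  pairwise_error_rate(b, a, rf)), 0.05)
})

test_that("the error-rate matrix is symmetric, equivariant under relabeling,
           and reflects planted group structure", {
  rf <- rf_control(ntree = 200, seed = 2)
  samples <- list(a1 = basin_points(120, c(-63, -43), seed = 1),
                  a2 = basin_points(120, c(-63, -43), seed = 2),
                  b1 = basin_points(120, c(-120, 130), seed = 3),
                  b2 = basin_points(120, c(-120, 130), seed = 4))
  m <- error_rate_matrix(samples, rf)
  expect_identical(unclass(m), t(unclass(m)))
  expect_equal(sum(!is.na(m)) / 2, choose(4, 2))
  # within-group errors (similar units) exceed between-group errors
  within <- c(m["a1", "a2"], m["b1", "b2"])
  between <- c(m["a1", "b1"], m["a1", "b2"], m["a2", "b1"], m["a2", "b2"])
  expect_gt(min(within), max(between))
  # permuting the input order permutes rows/columns consistently
  m2 <- error_rate_matrix(samples[c(3, 1, 4, 2)], rf)
  expect_equal(unclass(m2)[rownames(m), colnames(m)], unclass(m))
  expect_error(error_rate_matrix(samples[1]), "at least 2")
  expect_error(error_rate_matrix(stats::setNames(samples, rep("x", 4))),
               "unique")
})

test_that("classical MDS recovers exact Euclidean configurations", {
  # equilateral triangle at side 1: two equal positive eigenvalues, third ~ 0
  tri <- matrix(1, 3, 3) - diag(3)
  # all-equal dissimilarities also trip the degeneracy flag, by design
  expect_warning(emb <- mds_embed(1 - tri, k = 2), "degenerate")
  expect_equal(emb$eig[1], 1)
  expect_equal(emb$eig[2], 1, tolerance = 1e-9)
  expect_lt(abs(emb$eig[3]), 1e-9)
  # planar point set fed through its distance matrix: recovered up to
  # rotation/reflection (Procrustes)
  skip_if_not_installed("vegan")
  set.seed(31)
  pts <- matrix(runif(20, 0, 0.4), 10, 2)
  d <- as.matrix(dist(pts))
  emb2 <- mds_embed(1 - d, k = 2)
  pro <- vegan::procrustes(pts, emb2$points, symmetric = FALSE)
  expect_lt(sum(pro$residuals^2), 1e-8)
  # and the embedded inter-point distances match the input exactly
  expect_equal(as.matrix(dist(emb2$points)), d, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("degenerate inputs are flagged", {
  flat <- matrix(0.5, 4, 4); diag(flat) <- NA
  dimnames(flat) <- list(letters[1:4], letters[1:4])
  expect_warning(mds_embed(flat), "degenerate")
  same <- structure(list(eig = c(1, 0), degenerate = FALSE,
                         transform = "one_minus",
                         points = matrix(1, 5, 2,
                                         dimnames = list(letters[1:5], NULL))),
                    class = "mds_embedding")
  expect_error(cluster_units(same), "degenerate")
})

test_that("clustering recovers planted partitions and selects k by
           silhouette with a parsimony tie-break", {
  set.seed(7)
  blob1 <- matrix(rnorm(20, 0, 0.05), 10, 2)
  blob2 <- matrix(rnorm(20, 3, 0.05), 10, 2)
  emb <- structure(list(eig = c(1, 0.5), degenerate = FALSE,
                        transform = "one_minus",
                        points = rbind(blob1, blob2)),
                   class = "mds_embedding")
  rownames(emb$points) <- paste0("u", 1:20)
  cl <- cluster_units(emb)
  expect_equal(cl$k, 2L)
  expect_equal(adjusted_rand(cl$classes, rep(1:2, each = 10)), 1)
  expect_error(cluster_units(emb, k = 21), "exceeds")
})

test_that("equivalence queries respect the partition", {
  m <- load_table1()
  cl <- cluster_units(mds_embed(m))
  eq <- equivalent_units(cl, "gfgg1")
  expect_setequal(eq, c("gtg1", "gvg1", "gtgg1", "gvgg1"))
  expect_false("gfgg1" %in% eq)
  # symmetry: b in eq(a) <=> a in eq(b)
  for (lab in names(cl$classes))
    for (other in equivalent_units(cl, lab))
      expect_true(lab %in% equivalent_units(cl, other))
  expect_error(equivalent_units(cl, "zzz9"), "unknown")
})

test_that("planted word classes are recovered exactly from generated
           ensembles", {
  ens <- planted_word_ensembles(n_conf = 200, seed = 100)
  m <- error_rate_matrix(unit_samples(ens), rf_control(ntree = 200, seed = 5))
  cl <- cluster_units(mds_embed(m))
  truth <- rep(c(1, 2), 3)  # unit 1 alphaR-heavy, unit 2 beta-heavy
  expect_equal(cl$k, 2L)
  expect_equal(adjusted_rand(cl$classes, truth), 1)
  # similar units are harder to tell apart than dissimilar ones
  same <- c(m["gtg1", "gvg1"], m["gtg2", "gvg2"], m["gtg1", "fgg1"])
  diff <- c(m["gtg1", "gtg2"], m["gvg1", "fgg2"], m["gtg1", "gvg2"])
  expect_gt(min(same), max(diff))
})
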