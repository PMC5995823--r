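test_that("minimal fragment lengths follow the integer-truncation formulas", {
  expect_equal(minimal_fragment_lengths(3), c(n1 = 3L, n2 = 2L))
  expect_equal(minimal_fragment_lengths(5), c(n1 = 4L, n2 = 3L))
  expect_equal(minimal_fragment_lengths(10), c(n1 = 6L, n2 = 6L))
  expect_error(minimal_fragment_lengths(2), ">= 3")
})

test_that("splice plans reproduce the reference unit mappings", {
  # pentapeptide from two tetrapeptides: N supplies units 1-2, C units 3-4
  # from its units 2-3; junction (2, 3)
  p54 <- make_splice_plan(5, 4, 4)
  expect_equal(p54$n_target, 1:2)
  expect_equal(p54$c_target, 3:4)
  expect_equal(p54$c_source, 2:3)
  expect_equal(p54$junction, c(2L, 3L))
  # tetrapeptide from two tetrapeptides: C supplies unit 3 from its unit 3
  p44 <- make_splice_plan(4, 4, 4)
  expect_equal(p44$n_target, 1:2)
  expect_equal(p44$c_target, 3L)
  expect_equal(p44$c_source, 3L)
  expect_equal(p44$junction, c(2L, 3L))
  # tripeptide from two tripeptides
  p33 <- make_splice_plan(3, 3, 3)
  expect_equal(p33$n_target, 1L)
  expect_equal(p33$c_target, 2L)
  expect_equal(p33$c_source, 2L)
  expect_equal(p33$junction, c(1L, 2L))
  expect_error(make_splice_plan(8, 4, 4), "too short")
  expect_error(make_splice_plan(5, 2, 4), ">= 3")
})

test_that("every valid splice plan covers target units as a gap-free
           partition", {
  for (n in 3:12) for (n1 in 3:n) for (n2 in 2:n) {
    if (n1 + n2 < n + 2) next
    plan <- make_splice_plan(n, n1, n2)
    covered <- c(plan$n_target, plan$c_target)
    expect_equal(sort(covered), seq_len(n - 1))  # no gap, no double cover
    expect_true(all(plan$n_source >= 1 & plan$n_source <= n1 - 1))
    expect_true(all(plan$c_source >= 1 & plan$c_source <= n2 - 1))
    expect_equal(plan$junction, c(n1 - 2L, n1 - 1L))
  }
})

test_that("trial generation is the cross product of low-energy conformers
           and preserves parent units", {
  eN <- sample_ensemble("GFGG", 7, seed = 51)
  eC <- sample_ensemble("GFGG", 11, seed = 52)
  plan <- make_splice_plan(5, 4, 4)
  tr <- generate_trials(eN, eC, plan)
  expect_equal(nrow(tr$phi), 77L)
  # brute-force check over all trials: N-side units equal the N parent's
  for (t in seq_len(nrow(tr$phi))) {
    iN <- match(tr$parents$n_id[t], eN$id)
    iC <- match(tr$parents$c_id[t], eC$id)
    expect_equal(tr$phi[t, 1:2], eN$phi[iN, 1:2])
    expect_equal(tr$psi[t, 1:2], eN$psi[iN, 1:2])
    expect_equal(tr$phi[t, 3:4], eC$phi[iC, 2:3])
    expect_equal(tr$psi[t, 3:4], eC$psi[iC, 2:3])
  }
  # single-conformer ensembles give a single trial
  tr1 <- generate_trials(eN[1], eC[1], plan)
  expect_equal(nrow(tr1$phi), 1L)
  # only low-energy conformers are combined
  eN2 <- eN; eN2$energy[1:3] <- 11
  expect_equal(nrow(generate_trials(eN2, eC, plan)$phi), 44L)
  expect_error(generate_trials(sample_ensemble("GFG", 3, seed = 1), eC, plan),
               "plan needs")
})

test_that("junction screening matches the exhaustive oracle and never adds
           trials", {
  g2 <- two_basin_grammar()
  eN <- sample_ensemble("GFGG", 30, grammar = g2,
                        class_weights = two_basin_weights, seed = 21)
  eC <- sample_ensemble("GFGG", 30, grammar = g2,
                        class_weights = two_basin_weights, seed = 22)
  plan <- make_splice_plan(5, 4, 4)
  tr <- generate_trials(eN, eC, plan)
  bb <- make_grammar_benchmark(500, 500, margin = 30, seed = 31, grammar = g2)
  sp <- split_dataset(bb, 0.6, seed = 31)
  model <- train_grammar(sp$train, rf_control(seed = 31))
  surv <- screen_trials(tr, model)
  # exhaustive oracle: a trial survives iff its junction basins form an
  # allowed pair (planted basin paths are known for generated ensembles)
  bpN <- attr(eN, "basin_path"); bpC <- attr(eC, "basin_path")
  iN <- match(tr$parents$n_id, eN$id); iC <- match(tr$parents$c_id, eC$id)
  allowed <- paste(bpN[iN, 2], bpC[iC, 2]) %in%
    c("alphaR alphaR", "beta beta")
  expect_equal(nrow(surv$phi), sum(allowed))
  expect_equal(surv$parents, tr$parents[allowed, ], ignore_attr = TRUE)
  # a model accepting everything keeps every trial, order preserved
  with_mocked_bindings(
    screen_combo = function(model, combo) rep("accept", nrow(combo)),
    {
      all_surv <- screen_trials(tr, model)
      expect_equal(nrow(all_surv$phi), nrow(tr$phi))
      expect_equal(all_surv$parents, tr$parents)
    }
  )
})

test_that("near-duplicate trials collapse to the brute-force grouping", {
  plan <- make_splice_plan(3, 3, 3)
  mk <- function(phi, psi) {
    structure(list(phi = phi, psi = psi,
                   parents = data.frame(n_id = as.character(seq_len(nrow(phi))),
                                        c_id = "c"),
                   plan = plan, screened = rep("not-yet", nrow(phi))),
              class = "trial_set")
  }
  # identical trials collapse to one
  t2 <- mk(matrix(10, 2, 2), matrix(20, 2, 2))
  expect_equal(nrow(dedupe_trials(t2)$phi), 1L)
  # tol = 0 keeps all-distinct trials
  t3 <- mk(matrix(c(0, 50, 100), 3, 2), matrix(c(0, 50, 100), 3, 2))
  expect_equal(nrow(dedupe_trials(t3, tol = 0)$phi), 3L)
  # random trials: count matches a quadratic brute-force greedy grouping
  set.seed(61)
  phi <- matrix(sample(seq(-180, 175, by = 5), 400, TRUE) +
                  runif(400, -1, 1), 200, 2)
  psi <- matrix(sample(seq(-180, 175, by = 5), 400, TRUE) +
                  runif(400, -1, 1), 200, 2)
  tr <- mk(phi, psi)
  tol <- 3
  kept <- integer(0)
  for (i in 1:200) {
    dup <- any(vapply(kept, function(j)
      all(circular_diff(c(phi[i, ], psi[i, ]),
                        c(phi[j, ], psi[j, ])) <= tol), TRUE))
    if (!dup) kept <- c(kept, i)
  }
  expect_equal(nrow(dedupe_trials(tr, tol)$phi), length(kept))
})

test_that("fragment substitution returns a class-equivalent ensemble with
           provenance, or a useful error", {
  # build a partition in which ggg's units share classes with gfg's
  classes <- structure(list(
    classes = c(ggg1 = 1L, ggg2 = 2L, gfg1 = 1L, gfg2 = 2L,
                fgg1 = 3L, fgg2 = 2L),
    k = 3L, silhouette = NULL), class = "unit_classes")
  gfg <- sample_ensemble("GFG", 5, seed = 71)
  fgg <- sample_ensemble("FGG", 5, seed = 72)
  out <- substitute_fragment("GGG", classes, list(fgg, gfg))
  expect_equal(out$peptide, "GFG")
  expect_match(attr(out, "substitution"), "GFG standing in for GGG")
  expect_error(substitute_fragment("GGG", classes, list()), "no candidate")
  expect_error(substitute_fragment("GGG", classes, list(fgg)),
               "no class-compatible")
  # explicit target classes for fragments outside the learning set
  out2 <- substitute_fragment("AAA", classes, list(gfg),
                              target_classes = c(1L, 2L))
  expect_equal(out2$peptide, "GFG")
  expect_error(substitute_fragment("AAAA", classes, list(gfg),
                                   target_classes = c(1L, 2L)),
               "one class per target unit")
})

test_that("surviving trials export as an ensemble of the target sequence", {
  eN <- sample_ensemble("GFGG", 4, seed = 81)
  eC <- sample_ensemble("GFGG", 3, seed = 82)
  tr <- generate_trials(eN, eC, make_splice_plan(5, 4, 4))
  ens <- trials_as_ensemble(tr, "GGGGG")
  expect_s3_class(ens, "phipsi_ensemble")
  expect_equal(ens$peptide, "GGGGG")
  expect_equal(n_conformers(ens), 12L)
  expect_error(trials_as_ensemble(tr, "GGG"), "5 residues")
})
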