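toy_ensemble <- function(phi, psi, peptide = "GGG") {
  phipsi_ensemble(peptide, phi = phi, psi = psi,
                  energy = rep(0, nrow(phi)))
}

test_that("pair enumeration matches brute force with the 3-degree rule", {
  # single conformer: exactly one combo, labeled favorable (self-match)
  e1 <- toy_ensemble(cbind(10, 20), cbind(30, 40))
  d1 <- enumerate_pair_dataset(e1, c(1, 2))
  expect_equal(nrow(d1), 1L)
  expect_equal(d1$label, 1L)
  # two conformers at (0,0|0,0) and (100,100|100,100): 2x2 cross product,
  # only the two observed diagonal combos are favorable
  e2 <- toy_ensemble(cbind(c(0, 100), c(0, 100)), cbind(c(0, 100), c(0, 100)))
  d2 <- enumerate_pair_dataset(e2, c(1, 2))
  expect_equal(nrow(d2), 4L)
  expect_equal(sum(d2$label), 2L)
  expect_equal(d2$label[d2$phi_i == d2$phi_j], c(1L, 1L))
  # threshold boundary: a combination 2.9 deg off an observed conformer in
  # every angle is favorable; 3.1 deg off is not
  e3a <- toy_ensemble(cbind(c(0, 2.9), c(0, 2.9)), cbind(c(0, 2.9), c(0, 2.9)))
  d3a <- enumerate_pair_dataset(e3a, c(1, 2))
  expect_equal(sum(d3a$label), 4L)  # every cross combo within 2.9 of a parent
  e3b <- toy_ensemble(cbind(c(0, 3.1), c(0, 3.1)), cbind(c(0, 3.1), c(0, 3.1)))
  d3b <- enumerate_pair_dataset(e3b, c(1, 2))
  expect_equal(sum(d3b$label), 2L)  # only the two self-combinations
  expect_error(enumerate_pair_dataset(e1, c(1, 3)), "adjacent")
  expect_error(enumerate_pair_dataset(e1, c(2, 3)), "no unit 3")
})

test_that("enumeration size is the product of distinct unit values, summed
           over ensembles, and every observed conformer self-labels 1", {
  set.seed(12)
  ensembles <- lapply(1:3, function(i)
    sample_ensemble("GFGG", 12, seed = 40 + i))
  d <- enumerate_pair_dataset(ensembles, c(2, 3))
  expected <- sum(vapply(ensembles, function(e) {
    le <- low_energy(e)
    nrow(unique(cbind(le$phi[, 2], le$psi[, 2]))) *
      nrow(unique(cbind(le$phi[, 3], le$psi[, 3])))
  }, 0))
  expect_equal(nrow(d), expected)
  for (e in ensembles) {
    le <- low_energy(e)
    for (ci in seq_len(n_conformers(le))) {
      hit <- d$phi_i == le$phi[ci, 2] & d$psi_i == le$psi[ci, 2] &
        d$phi_j == le$phi[ci, 3] & d$psi_j == le$psi[ci, 3]
      expect_true(all(d$label[hit] == 1L))
    }
  }
})

test_that("the stratified split respects fractions, determinism and
           degenerate inputs", {
  b <- make_grammar_benchmark(60, 40, margin = 30, seed = 3)
  sp <- split_dataset(b, 0.6, seed = 5)
  expect_equal(nrow(sp$train), 60L)
  expect_equal(nrow(sp$holdout), 40L)
  expect_equal(sum(sp$train$label == 1), 36L)  # stratified: 60% of 60
  sp2 <- split_dataset(b, 0.6, seed = 5)
  expect_identical(sp, sp2)
  sp3 <- split_dataset(b, 0.6, seed = 6)
  expect_false(identical(sp, sp3))
  expect_error(split_dataset(b, 1.0), "strictly")
  expect_error(split_dataset(b, 0), "strictly")
  one_label <- b[b$label == 1, ]
  expect_error(split_dataset(one_label, 0.6), "both labels")
})

test_that("the grammar is learnable to below 2% on well-separated synthetic
           combinations and predictions are deterministic", {
  b <- make_grammar_benchmark(300, 300, margin = 30, seed = 13)
  sp <- split_dataset(b, 0.6, seed = 13)
  m <- train_grammar(sp$train, rf_control(ntree = 300, seed = 13),
                     holdout = sp$holdout)
  expect_lt(m$in_sample_error, 0.02)
  expect_lt(m$out_of_sample_error, 0.02)
  # determinism: retraining on the same data gives the same predictions
  m2 <- train_grammar(sp$train, rf_control(ntree = 300, seed = 13),
                      holdout = sp$holdout)
  expect_identical(screen_combo(m, sp$holdout[, 1:4]),
                   screen_combo(m2, sp$holdout[, 1:4]))
  expect_identical(screen_combo(m, sp$holdout[, 1:4]),
                   screen_combo(m, sp$holdout[, 1:4]))
  expect_error(train_grammar(sp$train[sp$train$label == 1, ]), "both")
})

test_that("uninformative labels yield chance-level error", {
  set.seed(17)
  b <- make_grammar_benchmark(300, 300, margin = 30, seed = 17)
  b$label <- sample(b$label)  # destroy the signal
  sp <- split_dataset(b, 0.6, seed = 17)
  m <- train_grammar(sp$train, rf_control(ntree = 200, seed = 17),
                     holdout = sp$holdout)
  expect_lt(abs(m$out_of_sample_error - 0.5), 0.12)
})

test_that("screening accepts training positives and rejects planted
           disallowed combinations", {
  b <- make_grammar_benchmark(300, 300, margin = 30, seed = 19)
  sp <- split_dataset(b, 0.6, seed = 19)
  m <- train_grammar(sp$train, rf_control(ntree = 300, seed = 19))
  pos <- sp$train[sp$train$label == 1, ][1:20, ]
  expect_true(all(screen_combo(m, pos[, 1:4]) == "accept"))
  # combos deep inside a disallowed basin pair: alphaR followed by beta is
  # not in the default allowed set
  deep <- cbind(-63, -43, -120, 130)
  expect_equal(screen_combo(m, deep), "reject")
  expect_error(screen_combo(list(), deep), "trained")
})

test_that("the learned rule is stable across training fractions", {
  b <- make_grammar_benchmark(300, 300, margin = 30, seed = 23)
  rep <- stability_check(b, c(0.5, 0.6, 0.7),
                         rf_control(ntree = 300, seed = 23), seed = 23)
  expect_equal(nrow(rep), 3L)
  expect_true(all(rep$in_sample_error < 0.02))
  expect_true(all(rep$out_of_sample_error < 0.02))
  expect_true(all(rep$below_threshold))
  expect_equal(rep$seed, 23L + 1:3)  # per-fraction seeds are reported
  empty <- stability_check(b, numeric(0))
  expect_equal(nrow(empty), 0L)
})
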