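# Shared generators for planted-structure fixtures.  Everything is built in
# code at test time; seeds are fixed so expectations are stable.

# grammar with every basin pair allowed: units keep their planted marginal
# basin weights (used by word-classification fixtures)
free_grammar <- function()
  grammar_spec(as.matrix(expand.grid(default_basins()$name,
                                     default_basins()$name)))

# three small peptides whose unit 1 follows an alphaR-heavy profile and
# unit 2 a beta-heavy profile; planted classes are c(1, 2) per peptide
planted_word_ensembles <- function(n_conf = 200, seed = 100) {
  wA <- c(0.6, 0.2, 0.2, 0, 0)
  wB <- c(0.1, 0.6, 0.1, 0.2, 0)
  peps <- c("GTG", "GVG", "FGG")
  lapply(seq_along(peps), function(i)
    sample_ensemble(peps[i], n_conf, class_weights = rbind(wA, wB),
                    grammar = free_grammar(), seed = seed + i))
}

# two-basin grammar whose allowed and disallowed combination regions are
# separated by construction (alphaR and beta are ~57 deg apart in phi and
# ~173 deg in psi, far beyond the 3 sd = 30 deg basin radius)
two_basin_grammar <- function()
  grammar_spec(rbind(c("alphaR", "alphaR"), c("beta", "beta")))

two_basin_weights <- c(1, 1, 0, 0, 0)

# draw (phi, psi) samples around a centre, for unit-sample fixtures
basin_points <- function(n, centre, sd = 10, seed = 1) {
  set.seed(seed)
  cbind(phi = wrap_angle(centre[1] + rnorm(n, 0, sd)),
        psi = wrap_angle(centre[2] + rnorm(n, 0, sd)))
}

adjusted_rand <- function(a, b) {
  # small self-contained adjusted Rand index
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab)); si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab))); n <- comb2(sum(tab))
  exp_idx <- si * sj / n
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
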