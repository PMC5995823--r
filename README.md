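# pepgrammar

Machine-learning support for "divide and conquer" peptide conformation
search, in R.

Finding the low-energy conformers of even a short peptide is a search over
a high-dimensional torus of backbone dihedral angles. A divide-and-conquer
search sidesteps the exponential cost of systematic enumeration: determine
the conformer ensembles of two short overlapping fragments, then splice
every pair of fragment conformers into a trial structure of the target and
keep only the trials whose junction looks like something a real peptide
would do. `pepgrammar` implements the two statistical learning components
that make this practical, plus the splicing machinery around them:

* **Words.** The (φ, ψ) dihedral pair of one residue is a *unit* (unit *i*
  of peptide X₁…Xₙ belongs to residue *i* + 1, written e.g. `gfgg2`). For
  every pair of units, a random forest is trained to tell their (φ, ψ)
  samples apart; its out-of-bag error rate *e* measures similarity (e → 0.5
  means indistinguishable). Classical (Torgerson) multidimensional scaling
  of the dissimilarity d = 1 − e followed by silhouette-guided
  agglomerative clustering groups units into equivalence classes — the
  licence for substituting one fragment's ensemble for another's.
* **Grammar.** Adjacent-unit combinations (φᵢ, ψᵢ, φᵢ₊₁, ψᵢ₊₁) observed in
  low-energy conformers (within 10 kcal/mol of the minimum) are favorable;
  combinatorial recombinations of the same unit values that match no
  observed conformer within 3° per angle are not. A random forest trained
  on these labels screens splice junctions, discarding unfavorable trial
  structures before any expensive geometry optimization.

Around the core: an internal-coordinate (NeRF) backbone builder and
dihedral extractor (exact round trip to 10⁻⁶ °), multi-model PDB /
multi-frame XYZ / CSV ensemble I/O, Gaussian-broadened density-of-states
curves φ(x) = (1/(α√π))·exp(−(x−E)²/α²) with α = 0.24 kcal/mol, a
trial-count cost model, and a synthetic Ramachandran-basin generator that
plants known word classes and grammar rules so every claim is testable
without external data.

The package ships the published 19-unit pairwise error-rate matrix of the
tri-/tetrapeptide learning set (GTG, GVG, VGG, FGG, MGG, GVGG, GTGG, GFGG)
as a plain-text fixture.

## Worked example

```r
library(pepgrammar)

# words: embed the packaged error-rate matrix and cluster the units
m   <- load_table1()
emb <- mds_embed(m)
emb
#> classical MDS embedding ( 19 units, transform: one_minus )
#>   leading normalized eigenvalues: 1, 0.57, 0.35, 0.23, 0.2
cl <- cluster_units(emb)
cl
#> phi-psi unit classes (k = 3 )
#>   class 1 : gvgg1, gtgg1, gfgg1, gtg1, gvg1
#>   class 2 : gvgg2, gtgg2, gfgg2, vgg1, mgg1, fgg1
#>   class 3 : gvgg3, gtgg3, gfgg3, gtg2, gvg2, vgg2, mgg2, fgg2
equivalent_units(cl, "gfgg1")
#> [1] "gvgg1" "gtgg1" "gtg1"  "gvg1"
```

The two leading eigenvalues dominate the spectrum, so a 2D map is a fair
picture of unit similarity, and the three classes separate units by their
position in the peptide: class 1 holds first units flanked by glycines,
class 2 second units, class 3 C-terminal units.

```r
# grammar: learn the combination rule on a planted synthetic benchmark
b     <- make_grammar_benchmark(500, 500, margin = 30, seed = 1)
sp    <- split_dataset(b, 0.6, seed = 1)
model <- train_grammar(sp$train, rf_control(ntree = 500, seed = 1),
                       holdout = sp$holdout)
model
#> phi-psi combination grammar (random forest, 500 trees)
#>   trained on 600 combinations; in-sample error 0.0000 (OOB 0.0083)
#>   out-of-sample error 0.0100 on 400 held-out combinations

# search: splice two tetrapeptide ensembles into pentapeptide trials
eN <- sample_ensemble("GFGG", 50, seed = 2)
eC <- sample_ensemble("GFGG", 50, seed = 3)
plan <- make_splice_plan(5, 4, 4)
plan
#> splice plan: target n = 5  from fragments n1 = 4 , n2 = 4
#>   N fragment units 1-2 -> target units 1-2
#>   C fragment units 2-3 -> target units 3-4
#>   junction screened: target units ( 2 , 3 )
surv <- screen_trials(generate_trials(eN, eC, plan), model)
surv
#> trial set: 1660 trial structures of 4 units
#>   screening status: accept = 1660
```

Of the 50 × 50 = 2500 spliced trials, 1660 survive the junction screen;
`trials_as_ensemble()` + `write_ensemble()` turn the survivors into a
multi-model PDB for external optimization.

A command-line wrapper (`exec/pepgrammar`) exposes the same pipeline as
subcommands `synth`, `words`, `grammar`, `search`, `dos` and `cost`, each
writing a JSON manifest of its fully-resolved configuration.

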