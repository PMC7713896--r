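---
title: "Methods: sketch-based distances and their transformation into phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sketch-based distances and their transformation into phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skimer)
```

## The problem

Whole-genome phylogenies are classically built from multiple sequence
alignments, which become impractical for large sets of multi-megabase
assemblies.  skimer implements the alignment-free alternative: each genome is
reduced to a MinHash *bottom sketch* of its canonical k-mers, sketch overlap
estimates the Jaccard index $j$ of the full k-mer sets, $j$ is converted to an
uncorrected p-distance, and the p-distance is transformed into a proper
evolutionary distance from which a tree is reconstructed.  The package also
contains the machinery needed to validate each link of that chain by
simulation.

## From sketches to p-distances

For genomes $x, y$ with canonical k-mer sets $K_x, K_y$, the Jaccard index
$j = |K_x \cap K_y| / |K_x \cup K_y|$ relates to the proportion $p$ of
differing sites through

$$p = 1 - \left(\frac{2j}{j+1}\right)^{1/k}.$$

Bottom sketches make $j$ cheap: hash every canonical k-mer and keep the
$\sigma$ smallest distinct values.  The merged estimator
(`estimate_jaccard()`) takes the $\sigma$ smallest values of the union of two
sketches and counts how many occur in both.  Two parameters matter:

* **k-mer size `k`** (default derived from `q`): must be large enough that a
  shared k-mer is evidence of homology rather than chance.  `choose_k(g, q)`
  returns $\lceil \log_4(g(1-q)/q) - 0.5\rceil$, the smallest k keeping the
  random-match probability below `q` for genomes of length `g`; `q` between
  1e-3 and 1e-12 maps typical bacterial genome lengths to k between 16
  and 31.  Larger k also raises the risk of the useless estimate
  $\hat\jmath = 0$ between distant genomes.
* **sketch size `sigma`** (default `s = 0.5` of the mean genome length):
  controls the sampling error of $\hat\jmath$.  We follow the convention of
  setting it as a fraction `s` of the *mean* genome length of the set, while
  `k` is resolved against the *largest* genome — the conservative choice when
  the two rules disagree.

The hash is a MurmurHash3-style 64-bit finalizer applied to the
2-bit-packed canonical k-mer (lexicographic min of the k-mer and its reverse
complement, which makes sketches strand-independent), XORed with a scrambled
seed (default 42).  Values are truncated to their top 53 bits so that R
doubles — and the flat sketch file format — represent them exactly; at
desk-scale k-mer counts the collision probability is negligible.  Windows
containing ambiguous residues are skipped, and windows never span contig
boundaries of multi-record FASTA input.

## From p-distances to evolutionary distances

Three transformations of a p-distance $p$ into an expected number $d$ of
substitutions per site are provided, in increasing model richness:

* **Poisson correction (PC)**: $d = -\ln(1 - p)$.
* **Equal input (EI / F81)**: $d = -b_1 \ln(1 - p/b_2)$ with
  $b_1 = 1 - \sum_r \pi_r^2$ from the equilibrium composition and
  $b_2 = 1 - \sum_r \pi_r^x \pi_r^y$ from the pair's compositions.  Equal
  frequencies give $b_1 = b_2 = 0.75$; GC- and AT-biased compositions such
  as (0.10, 0.30, 0.40, 0.20) and (0.40, 0.10, 0.10, 0.40) give 0.70
  and 0.66.
* **EI + Γ**: $d = a\,b_1\,[(1 - p/b_2)^{-1/a} - 1]$, where $a$ is the shape
  of a mean-1 Gamma distribution of rates across sites.  As $a \to \infty$
  this converges to the EI form (and `a = Inf` dispatches to it exactly);
  for fixed $p$ it is decreasing in $a$.  We read the leading coefficient as
  the *product* $a \cdot b_1$: only that reading has the correct
  large-$a$ limit and reduces to the standard F81+Γ estimator.  Under equal
  frequencies it is the exact inverse of the Jukes–Cantor+Γ expected
  p-distance, which the test suite checks to 1e-9 and uses as a
  parameter-recovery oracle for the fitter below.

`fit_equiv_a()` finds the shape $a$ whose EI+Γ curve best matches an
arbitrary target $p \mapsto d$ relationship by least squares.  The protocol
is deliberately fixed: a uniform $p$ grid on $(0, 0.35]$ with step 0.001
(0.35 being the practical ceiling of sketch-based p-distance estimation),
unweighted SSE, and bracketed scalar minimisation on $\log a \in
[\ln 0.01, \ln 100]$.  Fits are invariant to halving the grid step to within
1e-3.  Two applications recomputed by `scripts/acceptance.R`:

* the EI+Γ curve with $a = 0.291$ (the Gamma-regime fit to GTR+Γ distances)
  evaluated on an upward-biased estimate $\hat p = 1.15\,p$ is matched by a
  larger shape near 0.43 ($b = 0.70$) — quantifying how sketch bias must be
  compensated by inflating $a$;
* the legacy double-log formula $\delta = -b_1\ln(1 + \ln(1-p)/b_2)$
  (an EI correction mistakenly applied to an already-Poisson-corrected
  value) is approximated on $p \le 0.35$ by EI+Γ with shape near 1.1–1.2
  ($b = 0.75$), explaining why pipelines that used $\delta$ still produced
  reasonable trees.

Entries that cannot be transformed are explicit missing states, never
accidental NaN: $\hat\jmath = 0$ (no information) and $p \ge b_2$ (outside
the model's range) are recorded as such in the distance matrix.
`impute_missing()` fills them with
$d_{uv} = \min_x (d_{xu} + d_{xv})$ over third taxa with both legs present —
an upper bound justified by the triangle inequality.  All imputations read
only original entries (no chaining), so the result is order-independent.

## The simulator

`evolve_pair()` and `evolve_along_tree()` implement GTR(+Γ) evolution with
indels.  The generator $Q_{ij} = r_{ij}\pi_j$ is normalised to one expected
substitution per site per unit branch length, so branch lengths are directly
comparable across models.  Design choices worth stating:

* Pairs are simulated along a **single branch** with the ancestor as one
  endpoint; by time reversibility this is equivalent to two branches of
  $d/2$ from a common ancestor (checked in the tests).
* Rate heterogeneity uses **continuous** per-site Gamma rates rather than
  discrete categories; the analytic expectation `analytic_p()` uses the
  matching eigenvalue closure $(1 - \lambda d/a)^{-a}$, so simulation and
  expectation agree exactly in distribution, not just approximately.
* **Indels**: insertion and deletion events are drawn independently, each
  Poisson with mean `indel_rate * d * L` (rate 0.01 per substitution by
  convention), positions uniform, lengths Zipf(1.5) truncated to
  [1, 50000].  Substitutions are applied first, then deletions, then
  insertions — a simplification of the interleaved-in-time process that
  leaves the marginal substitution process exact and only approximates the
  indel-substitution interaction, which none of the downstream statistics
  depend on.  Site rates do not modulate indels.  Inserted sites draw fresh
  compositions and rates.
* `true_p` is computed over alignment columns in which both rows hold a
  residue, so it measures substitutions only.
* Defining $d$ as *substitution* events per site (indels not counted in
  branch length) matches the simulator convention used for the published
  relative-length figures only approximately; full-scale reproduction of
  those particular values is out of scope here.

Because the 142 real maximum-likelihood GTR parameter sets behind the
published benchmarks are external data deposits, `gtr_rate_library()` ships
a small *synthetic* library of transition-biased exchangeabilities with
Gamma shapes spanning the reported range [0.162, 0.422] (mean
estimate 0.314).  It emulates realistic substitution processes; it does not
reproduce any specific genus's estimates.

## Tree reconstruction

`ratchet_search()` reconstructs a phylogeny from a complete distance matrix
under the balanced minimum-evolution (BME) criterion: Pauplin's balanced
length $\sum_{u<v} 2^{1 - t_{uv}} d_{uv}$, with $t_{uv}$ the topological
path length.  The search starts from the neighbor-joining tree (negative
branches clamped to zero), hill-climbs through nearest-neighbor
interchanges, and escapes local optima with a ratchet: multiply all
distances by independent $U(1-\varepsilon, 1+\varepsilon)$ noise
(default $\varepsilon = 0.2$), climb on the perturbed matrix, re-climb and
re-score on the original, keep the best tree seen.  Defaults are 100 rounds;
the desk-scale benchmarks in this package use 5–10 rounds, which already
recover essentially all additive and low-noise matrices (the search can
never end worse than its NJ start, which is itself exact on additive input).
Final branch lengths are ordinary least squares with negative estimates
clamped to zero.  Ties in the NNI neighborhood are broken by first-best
order, making the whole search deterministic given the seed.

## What the benchmarks show (and what they do not)

The simulation benchmarks in the test suite run at reduced scale: sequence
lengths of 1–2 × 10^5 bases instead of 5 × 10^6, tens of pairs per condition
instead of 200, and 20 ten-leaf reference trees with branch lengths drawn
uniformly from [0.03, 0.16] (diameters roughly 0.7–1.2 substitutions per
site) instead of 142 real genus trees of 10–154 taxa.  The branch-length
range is the deepest that desk-scale sketches can still resolve:
resolvability of a pair scales with σ·j, and at σ ≈ 5 × 10^4 pairs beyond
p ≈ 0.3 collapse to zero-Jaccard estimates (diameters beyond ~1.2 leave
whole rows unresolvable even by triangle imputation), whereas the
multi-million-hash sketches of full-scale runs keep such pairs
informative.  One consequence is that at desk scale the recovery
comparison between transformations is often a tie near 100% — the regime
in which the Poisson correction actively loses trees needs the deeper
matrices only full-scale sketches support.  All statistics involved are length-scalable, and the
full-scale protocol remains reachable through plain arguments
(`L`, `n_pairs`, `d_grid`).  At desk scale the suite demonstrates:

* near-perfect correlation (Fisher-z confirmed $r > 0.99$) between true and
  sketch-estimated p-distances up to $p \approx 0.25$ with $k = 21$,
  $s = 0.2$;
* a through-origin regression slope $\beta > 1$ once indels are simulated —
  sketch p-distances are upward-biased because indels disrupt k-mer
  sharing;
* fitted equivalence shapes that cleanly separate regimes: large
  ($a > 3$) for homogeneous GTR, small ($a \approx 0.29$) for GTR+Γ with
  shape 0.314, and the bracket ceiling for exactly-EI (Jukes–Cantor) input;
* under strong rate heterogeneity ($\alpha \approx 0.3$), the EI+Γ
  transformation with $a \in [1, 2]$ recovers at least as many reference
  topologies as the Poisson correction.

Synthetic genomes are i.i.d. draws from equilibrium composition; they lack
repeats, horizontal transfer, rearrangements and assembly artifacts, all of
which degrade real-world sketch distances in ways these tests cannot
detect.  Passing the suite therefore validates the statistical chain, not
robustness to real genome structure.

## Numerical notes and limitations

* `p_from_jaccard(0, k)` is `NA` by design: a zero Jaccard estimate carries
  no distance information.
* `k` is limited to 31 by the 2-bit packing; this covers the useful range
  (random-match probabilities down to 1e-12 for 5 Mb genomes).
* The 53-bit hash truncation makes hash collisions ~2000× more likely than
  full 64-bit hashing; at 10^7 distinct k-mers the expected number of
  colliding pairs is still ≪ 1.
* `fit_equiv_a` reports the bracket endpoint (100) when the target is
  (numerically) an exact EI curve; this is informative, not an error.
* BME search uses NNI moves only; SPR/TBR, branch supports and rooting are
  out of scope.
* Imputed distances are upper bounds; matrices with many missing entries
  (very distant genomes, overly large `k`) will distort the tree and should
  be re-sketched with smaller `k` instead.
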