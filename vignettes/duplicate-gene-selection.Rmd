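---
title: "Selection inference for duplicated genes: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection inference for duplicated genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupsel)
```

## The scientific question

When a gene duplicates, the fate of the two copies is written in their
substitution patterns. Under *neofunctionalization* (NF) one copy acquires a
new adaptive function under positive selection while the other keeps the
ancestral role under purifying selection; under *escape from adaptive
conflict* (EAC) both copies evolve under positive selection, one improving
the ancestral and one the novel function; under *concerted
neofunctionalization* (CN) both copies are selected for novel functions; and
*subfunctionalization* (SF) partitions the ancestral function essentially
neutrally. `dupsel` implements the two complementary lines of molecular
evidence used to distinguish these modes in gene families such as the
glucosinolate-sulfatase (GSS) cluster of the diamondback moth, together with
the decision table that turns the evidence into a retention-mode call:

1. **Phylogeny-based tests**: branch-site codon substitution models fitted by
   maximum likelihood, comparing an alternative allowing a site class with
   $\omega_2 \ge 1$ on a designated foreground branch against a null with
   $\omega_2 = 1$, with Holm–Bonferroni correction across the branches of a
   clade scan.
2. **Population-based tests**: McDonald–Kreitman (MK) contrasts of
   within-species polymorphism against divergence from outgroups, orthologs
   and *reconstructed ancestral sequences*, with Jukes–Cantor distance
   correction of the divergence counts and a conservative min–max aggregation
   over a suite of reconstruction models.

## The codon model

Substitution between sense codons $i \ne j$ follows the usual
Goldman–Yang-style generator

$$
q_{ij} =
\begin{cases}
0 & \text{more than one position differs, or } j \text{ is a stop} \\
\pi_j & \text{synonymous transversion} \\
\kappa \pi_j & \text{synonymous transition} \\
\omega \pi_j & \text{nonsynonymous transversion} \\
\omega \kappa \pi_j & \text{nonsynonymous transition.}
\end{cases}
$$

Codon frequencies $\pi$ default to F3×4 (the product of position-specific
nucleotide frequencies estimated from the alignment, renormalised over the 61
sense codons); `equal` and `F61` modes are available. The model is
reversible, so likelihoods are invariant to root placement and $P(t) =
e^{Qt}$ is computed through the symmetric eigendecomposition of
$\mathrm{diag}(\sqrt\pi)\, Q\, \mathrm{diag}(1/\sqrt\pi)$.

Under M0 a single $\omega$ applies everywhere. The branch-site model A mixes
four site classes $\{0, 1, 2a, 2b\}$ with proportions
$(p_0,\, p_1,\, p_{2a},\, p_{2b})$, where classes 2a/2b take the remainder
$1 - p_0 - p_1$ split proportionally to $p_0 : p_1$. Background branches see
$\omega_0 \le 1$ (classes 0, 2a) or $\omega_1 = 1$ (classes 1, 2b); the
foreground branch sees $\omega_2 \ge 1$ in classes 2a/2b.

**Rate scaling.** All class generators share one scale factor, fixed so that
the *background* mixture has mean rate 1 at stationarity. Branch lengths are
therefore expected substitutions per codon on background branches, and sites
in the selected classes genuinely evolve faster on the foreground branch —
the property the branch-site test draws its power from. (Normalising each
class generator separately would silently remove that rate elevation.)

## Likelihood, fitting and the branch-site test

Likelihoods are computed by Felsenstein pruning over the 61 sense-codon
states with site-pattern compression; columns containing gaps or ambiguities
are dropped (the intended inputs are gap-stripped alignments). The pruning
core is validated in the test suite against an independent brute-force
enumeration of all internal-node states on small trees (`enumerate_loglik`),
to $10^{-10}$.

`fit_codon_model()` maximises the likelihood by L-BFGS-B on transformed
parameters ($\log \kappa$, $\log \omega$, logit $\omega_0$,
$\log(\omega_2 - 1)$, additive-logistic $(p_0, p_1)$, $\log t$ per branch)
with multiple seeded starts; the best log-likelihood wins and the first
start wins exact ties. Convergence uses `factr = 1e8` (about $10^{-8}$
relative in the log-likelihood); gradients are forward finite differences on
the transformed scale.

`branch_site_lrt()` compares the alternative and null model A fits with the
statistic $2\Delta\ell$ clipped at zero and referred to $\chi^2_1$. This is
deliberately the conservative convention (the literature's alternative is a
50:50 mixture of $\chi^2_0$ and $\chi^2_1$); the package keeps it because
scan-level conclusions should err toward fewer false positives.

Two fitting strategies are offered:

* `branch_lengths = "m0"` (default): branch lengths are estimated once per
  dataset under M0 and shared by the null and alternative fits, $\kappa$ is
  profiled under M0 and pinned, and — importantly — the *foreground branch
  length stays free in both fits*. Freeing it on both sides prevents misfit
  of the shared lengths on the tested branch from masquerading as
  $\omega_2 > 1$ (in calibration runs, pinning it inflated the null
  rejection rate to ~10%; freeing it restores ~3% at a nominal 5%). This
  strategy makes 200-replicate calibration studies practical on one CPU.
* `branch_lengths = "estimate"`: full joint re-estimation under each model;
  in side-by-side runs the p-values match the default strategy closely.

`scan_branches()` applies the test to each branch of a clade and adjusts the
raw p-values with `stats::p.adjust(method = "holm")`.

`site_class_posteriors()` reports naive empirical-Bayes class posteriors at
the MLEs — the posterior of classes $\{0, 1, 2a, 2b\}$ per site, with
`p_selected` $= p_{2a} + p_{2b}$. This is a deliberate simplification of the
full Bayes-empirical-Bayes treatment: no hyperprior integration is
performed, so posteriors near the reporting threshold should be read
qualitatively.

## Ancestral reconstruction suites

`marginal_reconstruction()` computes, per site, the marginal posterior over
the 61 states at an internal node by combining the partial likelihoods below
the node with the likelihood flow from the rest of the tree (inside/outside
recursions), marginalised over site classes for branch-site fits. The MAP
codon is reported with its posterior; exact ties break toward the
lexicographically smallest codon and are flagged. Joint reconstruction is
not implemented — the downstream use (counting substitutions against a
reference) is served by marginal MAP sequences. Gap-dropped columns are
emitted as `---`.

Because ancestral states depend on the assumed selective regime,
`reconstruction_suite()` reconstructs the same node under a *suite* of
constrained models — typically neutral M0 plus branch-site models forcing
$\omega_2 > 1$ or $\omega_2 = 1$ onto key branches. Downstream MK tests then
report, over the suite, per-cell min–max ranges, the largest Neutrality
Index as an upper bound ("$\le$ NI$_{max}$") and the smallest $\chi^2$ as a
lower bound ("$\ge \chi^2_{min}$"): whatever the true history, the evidence
for adaptive divergence is at least this strong.

## The McDonald–Kreitman stack

Counting conventions (module-isolated so they can be swapped):

* **Pathway counts.** Differences between two codons are classified by
  enumerating all orderings of the differing positions, discarding orderings
  that pass through a stop codon, and averaging synonymous/nonsynonymous
  step counts (fractional counts). If *every* pathway is stop-blocked, the
  average is taken over all pathways with stop steps counted as
  nonsynonymous and the result is flagged — this keeps `syn + nsyn` equal to
  the Hamming distance for every pair.
* **Polymorphism.** Per column, distinct alleles are joined by a minimum
  spanning tree under codon Hamming distance (deterministic tie-breaks) and
  pathway counts are summed over its edges.
* **Divergence.** Only columns fixed within the sample are compared with the
  reference (the classic MKT convention; polymorphic columns contribute to
  polymorphism only).
* **Sites and distance correction.** Nei–Gojobori site counts (per codon:
  synonymous single-base changes / 3, stops counted nonsynonymous) supply
  the per-class denominators; divergence counts are Jukes–Cantor corrected
  per class, $d = -\tfrac34 \ln(1 - \tfrac43 p) \cdot \text{sites}$, with
  sites averaged between the sample consensus and the reference.
  Polymorphism counts are never corrected.
* **The test.** $NI = (P_n/P_s)/(D_n/D_s)$; Pearson $\chi^2$ without
  continuity correction on $[[P_s, P_n], [D_s, D_n]]$ (validated against the
  published worked examples, which match the uncorrected statistic); upper
  $\chi^2_1$ tail p-value. Zero cells flag NI as undefined rather than
  infinite. Display rounding follows the published tables: NI to 2 decimals,
  $\chi^2$ to 1, p to 3.

`pairwise_mk()` pools the two samples' polymorphism cells and takes
divergence between columns fixed in both samples. The printed contingency
tables of the motivating study ship as `gss_mk_counts()`; its documentation
records which published statistics recompute exactly from the printed
(rounded) inputs.

## The synthetic-data generator

`simulate_codon_alignment()` draws each site's class from the model-A
proportions, draws root codons from $\pi$, and evolves states down the tree
with the class- and branch-appropriate $\omega$ (shared rate scale, as in
the likelihood). The per-site true class is returned for calibration
oracles. `simulate_population_sample()` overlays Poisson numbers of
synonymous/nonsynonymous single-base polymorphisms (expectations
$\theta \times$ class sites) at distinct codon positions, each at a uniform
derived-allele frequency — a deliberate simplification with no coalescent
genealogy, sufficient for MK count structure; linkage, demography and
recombination are not emulated, so passing calibration here says nothing
about those features of real data. `simulate_divergence()` manufactures
diverged reference sequences the same way.

`scenario_presets()` fixes four seeded scenarios on a six-tip tree shaped
like a duplicated gene family (two paralog clades and an outgroup): `neutral`
($\omega_2 = 1$), `NF` (selection on one daughter stem), `EAC`/`CN`
(selection on both stems, distinguished by their function-annotation
fixtures). Defaults: 300 codons, $\kappa = 2$, $\omega_0 = 0.1$,
$p_0 = 0.72$, $p_1 = 0.18$ (10% of sites in the foreground classes),
$\omega_2 = 4$ on selected branches, equal codon frequencies. The tree
(tested daughter stem 0.70 substitutions/codon, sister stem 0.30, outgroup
0.35, within-clade branches 0.08–0.15) was designed once from two
considerations: the emulated family is deeply diverged (its printed
outgroup comparison implies roughly 2.9 substitutions/codon on the
outgroup-to-tip path, so a 0.7 stem is conservative), and the parent
endpoint of the tested branch must be resolvable from the root-side
lineages for a branch-site test to register repeated nonsynonymous hits.

## Operating characteristics and their limits

The validation suite (and `scripts/acceptance.R`) measures, at the preset
conditions:

* pruning and reconstruction against brute-force enumeration ($10^{-10}$);
* the null rejection rate of the branch-site LRT over 200 neutral
  replicates (expected at or below nominal under the conservative
  $\chi^2_1$ convention);
* its power over 100 replicates at $\omega_2 = 4$, 10% selected sites,
  300 codons;
* M0 recovery of $(\omega, \kappa)$ over 20 replicates of 500 codons;
* MK calibration over 100 replicates (mean NI near 1 under equal
  polymorphism/divergence intensity ratios, mean NI near $a/b$ otherwise,
  nominal $\chi^2$ rejection rates).

One caveat deserves emphasis: a large-sample run of the `NF` preset (3,000
codons) puts the LRT noncentrality near 4.6 per 300 codons, which caps the
test's power around 60–75% at these exact conditions on a six-taxon tree —
episodic selection on a single internal branch with 10% of sites at
$\omega_2 = 4$ is simply a modest signal at this alignment length. Power
rises quickly with more taxa, longer alignments or stronger/broader
selection; the empirical analyses this package re-implements used a
13-sequence alignment of 439 codons and reported test statistics of 8–35.

## Numerical and degenerate-input notes

* Transition-matrix rows are clamped to $[0, 1]$ and renormalised against
  rounding noise; `t = 0` returns the identity.
* Invariant alignments drive branch lengths to their lower bound
  ($10^{-7}$) and yield LRT statistics of 0 — flagged, not an error.
* Stop codons: internal stops are validation errors; a terminal stop column
  shared by all sequences is excluded from analysis rather than rejected.
* All-zero MK tables are errors; zero cells flag NI as undefined.
* Optimiser ties across restarts resolve to the earliest start, making fits
  reproducible for a given seed.
* The inside/outside reconstruction recursions run unscaled, which is safe
  for the tree sizes this package targets (tens of tips); the pruning core
  itself rescales per node and handles hundreds of tips.
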