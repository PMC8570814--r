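---
title: "polyseg: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polyseg: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyseg)
```

# Overview

`polyseg` estimates identity-by-descent (IBD) parental-homologue
inheritance probabilities in F1 populations of autopolyploids (and
diploids) from a phased linkage map and SNP dosage data, and uses them for
QTL interval mapping and meiotic diagnostics. The pipeline is

1. **IBD estimation** — HMM (`estimate_ibd_hmm`) or fast heuristic
   (`estimate_ibd_heuristic`), optionally interpolated onto a cM grid
   (`interpolate_ibd`);
2. **QTL analysis** — genome scan (`scan_qtl`), permutation threshold
   (`permutation_threshold`), automatic co-factor search
   (`cofactor_search`), QTL allele-configuration exploration
   (`explore_configurations`), per-homologue effect profiles
   (`homologue_effects`);
3. **Meiotic diagnostics** — pairing-configuration assignment
   (`count_valencies`), double reduction (`double_reduction_rate`),
   preferential-pairing tests (`test_preferential_pairing`),
   recombination detection (`count_recombinations`, `screen_outliers`),
   information content (`gic`) and dosage imputation (`impute_dosages`);
4. a **meiosis simulator** (`simulate_cross`) that provides ground truth
   for validation, and a CLI (`polyseg_main`).

# The inheritance model

## States and valencies

Each parent of ploidy $p$ contributes $p/2$ chromosomes to a gamete. A
*valency* describes how the parent's homologues paired in one meiosis:

- bivalent-only pairings are the perfect matchings of the $p$ homologues —
  1 for a diploid, 3 for a tetraploid, 15 for a hexaploid;
- with multivalents allowed, a tetraploid adds the quadrivalent (ABCD), and
  a hexaploid adds the 15 quadrivalent + bivalent combinations.

Given a valency, the *gamete state* records which homologue of each unit
the tracked gamete carries: 2 states per bivalent, and for a quadrivalent
the 10 multisets of size 2 of its four homologues. The four "doubled"
multisets (the same homologue twice) are double-reduction (DR) states.

## Transitions and emissions

Between adjacent markers at map distance $d$ cM the recombination fraction
is Haldane's $r = (1 - e^{-2d/100})/2$. Each bivalent switches its
transmitted homologue with probability $r$; a quadrivalent is modelled as
two chromatid lineages that independently stay with probability $1-r$ or
move to each of the other three homologues with probability $r/3$, with the
16 ordered lineage pairs aggregated onto the 10 unordered states. The full
transition matrix is the Kronecker product over units, and the maternal and
paternal chains combine as another Kronecker product. The exact
parametrization of the original method's multivalent transitions is not
published in full; this independent-lineage construction is validated
against an exhaustive path-enumeration oracle and by simulator recovery.

Emissions compare the offspring dosage implied by the joint gamete state
and the marker phase with the observed call: a correct class has
probability $1-\varepsilon$ and each other class $\varepsilon/p_{\rm off}$,
where $\varepsilon$ is the genotyping error prior (default 0.01; use up to
0.2 for noisy data). Missing calls emit 1 (uninformative). Probabilistic
dosage input mixes the class simplex with the error model. The initial
state distribution is uniform over gamete states.

## Estimation

For every valency pair the scaled forward–backward algorithm is run for
all offspring at once (the per-position computation is a matrix product
over individuals, which is what makes hexaploid crosses tractable).
Valency-pair posteriors are proportional to prior times marginal
likelihood; the prior places `multivalent_prior` (default 0.1) total mass
on multivalent configurations. IBD probabilities are posterior-weighted
expected homologue copy counts; the posterior mass on doubled states gives
per-position DR probabilities.

Offspring ploidies 2, 3, 4 and 6 are supported by the HMM; the heuristic
covers other ploidies. Every output satisfies the invariant that each
parent's expected contributions sum to half its ploidy (`validate_ibd`).

## The heuristic

Per marker and parent, the probability that each parental homologue was
transmitted is computed under uniform gamete draws, marginalizing the other
parent. Log-evidence is pooled across informative markers within a window
(default 20 cM) with Haldane distance-decay weights $1-2r(d)$,
exponentiated, and renormalized. Entries above 1 are resolved by
*water-filling*: capped entries stay at 1 and the remainder is shared
proportionally so the parent sum stays exactly $p/2$ (a naive
cap-then-renormalize loop can violate the sum). Evidence is floored at
1e-10 before taking logs. Positions with fewer than `min_informative`
informative markers in the window are flagged `low_confidence`.

# QTL mapping

At every position the (block-corrected) phenotype is regressed on the
homologue probabilities with the first homologue of each parent dropped
(per-parent probabilities sum to $p/2$, so the full design is collinear):
6 predictors for a tetraploid × tetraploid scan, 10 for hexaploid ×
hexaploid. Test statistics:

- $\mathrm{LOD} = (N/2)\log_{10}(\mathrm{RSS}_0/\mathrm{RSS}_1)$,
- $\mathrm{PVE} = 100\,(1-10^{-2\,\mathrm{LOD}/N})
  \equiv 100\,(1-\mathrm{RSS}_1/\mathrm{RSS}_0)$ (multi-QTL models use the
  RSS form of the joint fit).

Blocks are removed first (`block_correct`): residual mode (default) or
BLUEs; missing block observations are imputed from the block effect plus
the individual's mean deviation when at least half its blocks are observed.

The scan engine QR-decomposes each position's design once and projects all
response columns through it, so a 1000-permutation threshold costs little
more than 1000 extra response columns. The threshold is the conservative
ceiling-index percentile of the permutation maxima:
`sort(max_lods)[ceiling((1 - alpha) * n_perm)]`.

`cofactor_search` starts from the significant peaks of a plain scan,
evaluates every nonempty subset of them as co-factors ($2^n - 1$ models per
refinement pass, reported in `n_models`), re-locates each QTL at the
threshold-adjusted LOD maximum within `min_dist` of its previous estimate
(models containing a co-factor within `min_dist` of the QTL are skipped),
deduplicates peaks that merged, and repeats once. A single shared
permutation threshold is used across co-factor models.

`explore_configurations` enumerates the bi-allelic QTL configurations
(each parent's Q-subset excluding the full set; the no-Q configuration
excluded): $(2^{p_1}-1)(2^{p_2}-1)-1$ models, 224 for tetraploid ×
tetraploid. Each is scored by Gaussian BIC
$N\ln(\mathrm{RSS}/N) + k\ln N$ with $k = 2$. Complementary configurations
are exactly collinear and tie in BIC; ties (after rounding BIC to 1e-6) are
broken by fewer Q alleles.

# Meiotic diagnostics

- `count_valencies` assigns each meiosis its maximum-posterior valency when
  that posterior reaches the plausibility threshold (default 0.4).
- `test_preferential_pairing` counts predicted bivalent partners and tests
  each homologue's partner counts against the uniform expectation
  $n/(p-1)$ with a chi-square goodness-of-fit on $p-2$ degrees of freedom
  (raw and Bonferroni-adjusted p-values).
- `count_recombinations` tracks $d = X_a - X_b$ for each plausibly assigned
  bivalent pair; each sign change is one cross-over, placed at the midpoint
  of the flanking non-zero positions (zero plateaus count once, at the
  plateau midpoint). The expected reference is offspring ploidy × number of
  linkage groups (54 for a hexaploid with 9 LGs); `screen_outliers` flags
  individuals above `multiplier` (default 2) times that.
- `gic` computes $\mathrm{GIC}_j = 1 - (4/N)\sum_n P_{nj}(1-P_{nj})$ per
  homologue and position; with multivalents modelled, only
  bivalent-predicted offspring are included so $P$ stays in $[0,1]$.
- `impute_dosages` forms $\hat d = \sum_j X_j \cdot \mathrm{phase}_j$,
  rounds it, and sets calls missing when the exact value deviates from the
  rounded one by more than `rounding_threshold` (default 0.05). Estimating
  IBDs with a high error prior ($\varepsilon = 0.2$) first lets the HMM
  absorb genotyping errors so the imputation corrects them.

# The simulator

`simulate_cross` draws a phased map (equally spaced markers, a configurable
proportion of simplex × nulliplex markers, remaining patterns rejected if
non-segregating), then simulates each meiosis: a valency per parent
(quadrivalents with probability `multivalent_prob`; bivalent partners drawn
proportionally to a symmetric pairing-preference matrix), one chromatid
lineage per bivalent and two per quadrivalent, each a Poisson cross-over
process at 1/100 cM (Haldane-consistent). The two quadrivalent lineages
start on *distinct* homologues, so double reduction appears only distal to
exchanges — the expected terminal DR landscape rising away from the
centromere (placed at 0 cM). Genotyping errors flip a call to a uniformly
drawn different class. `as_ibd` wraps the true copy counts so all
downstream machinery can run on noiseless ground truth.

Known bias: the HMM's uniform initial distribution includes doubled states,
so it overestimates DR near the centromere relative to this terminal
mechanism; the rising-toward-telomere shape is recovered.

# Numerical choices worth knowing

- Markers at identical cM positions: inter-marker distances are floored at
  1e-4 cM so transition chains keep mixing.
- Grid interpolation uses natural cubic splines per homologue track,
  clipped to the valid range and renormalized per parent to the exact sum
  invariant.
- LOD is capped at 1e6 on degenerate perfect fits; RSS is floored at the
  smallest positive double.
- Valency enumeration order is deterministic, so valency posteriors
  round-trip through `write_ibd`/`read_ibd`.
- Test-suite problem sizes (e.g. 150 markers × 200 offspring for the
  imputation guarantee, 200 markers/LG for recombination recovery) reflect
  the intended operating range: markedly sparser maps degrade those
  guarantees.

# Reproducibility

Every CLI run writes a JSON metadata sidecar (command, parameters, package
version, input checksums). All stochastic steps accept explicit seeds;
results are independent of the number of worker processes because the
implementation is deterministic single-threaded BLAS-level code.
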