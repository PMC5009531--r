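---
title: "Predicting backbone flexibility from sequence: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting backbone flexibility from sequence: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind **flexseq**, the
choices that were genuinely open when the package was designed, and what
the synthetic test bed does and does not establish about behaviour on real
structures.

## From temperature factors to flexibility states

A crystallographic B-factor is $B = 8\pi^2 U^2$, where $U^2$ is the
mean-squares positional displacement of the atom in Å². The Cα value is
used as the residue's flexibility descriptor. Because refinements place
chains on different B scales, each chain is normalized independently,

$$b_i = \frac{B_i - \mu}{\sigma},$$

with $\mu$ and $\sigma$ computed over that chain's residues that have a
defined Cα B-factor. Two numerical decisions live here:

* **$\sigma$ is the population standard deviation** (denominator $N$).
  With it, the per-chain invariants — mean exactly 0, SD exactly 1 — hold
  to $10^{-9}$ even for the minimal two-residue case, and the affine
  invariance of $b$ under $B \mapsto cB + d$ ($c>0$) is exact.
* **Degenerate chains** (all B equal, or fewer than two defined values)
  have no meaningful $z$-scale; they raise an error, or are dropped with a
  warning in pipeline use.

States are assigned with thresholds $(-1.1, 2.2)$: rigid below, flexible
above, intermediate between. The inequalities are strict on both sides,
so a residue **exactly at a threshold is intermediate** — the literal
reading of "less than" / "greater than", and the tie-break least likely to
inflate the rare classes. A residue is *undetermined* when it has no CA
atom, no finite B-factor, or a non-standard identity; the corpus filter
removes chains shorter than 40 residues, eliminates undetermined residues,
and re-applies the length check afterwards (the conservative order of the
two rules).

### Why the three classes cannot be balanced

One might expect the thresholds to split residues into rough thirds. They
cannot, for any distribution: a z-scored variable satisfies the Chebyshev
bound $P(b > 2.2) \le 1/2.2^2 \approx 0.21$, and realistic right-skewed
shapes put the attainable flexible fraction nearer 3–10%. The reference
conditions therefore have a rigid minority, an intermediate majority and a
small flexible class, which matches the empirical observation that most
residues sit in the middle of the normalized-B distribution. Two
consequences are reflected in the tests: the "no-information" rate of a
classifier is the majority-class frequency, not $1/3$ (a permuted-label
network is compared against that rate), and per-state recall on the
flexible class is intrinsically noisy.

## Context potentials

For every labeled residue, singlet ($R_i$), doublet ($R_i R_{i+k}$) and
triplet ($R_i R_{i+k_1} R_{i+k_2}$) occurrences are counted in a 7-residue
window ($-3 \le k, k_1, k_2 \le 3$, nonzero; $k_1 < k_2$), conditioned on
the centre residue's state. Contexts that extend past a chain end are
skipped symmetrically in counting and in scoring — no padding token — so
the statistics and the scores always refer to the same event space.

The counts become mean-force potentials by inverse Boltzmann inversion
with additive-prior smoothing:

$$\hat f(C \mid x) = \frac{m\, f_{\mathrm{obs}}(C \mid x) + w\, f(C)}{m + w},
\qquad U(C, x) = -\ln \frac{\hat f(C \mid x)}{f(C)},$$

where $m$ is the context's total count, $f(C)$ the corpus-wide state
frequency, and $w$ a pseudo-observation mass (default **10**). The
functional form is the standard knowledge-based-potential construction;
the smoothing is required because the triplet table
($3 \times 15 \times 20^3$ cells) is unavoidably sparse: a never-observed
context sits exactly at $U = 0$ (no preference), $w \to 0$ recovers the
raw log-ratio, and $w \to \infty$ flattens all potentials. The temperature
factor $kT$ is absorbed into the (dimensionless) unit of $U$.

The per-residue score in state $C$ sums the in-range terms
($1 + 6 + 15 = 22$ for an interior residue). Because the network wants
bounded inputs, the three sums are presented as
$\mathrm{SCRS}(C) = e^{-U(C)} / \sum_{C'} e^{-U(C')}$ — a point on the
3-simplex, commensurate with the probability-valued features. Unknown
residues (`X`) contribute no counts and score 0 in every cell.

## Encoding and classifier

Each residue carries 34 features in fixed order: 20 PSSM log-odds mapped
through the logistic $1/(1+e^{-x})$ (the conventional squashing for
profile-fed networks; the raw integers are unbounded), 3 SCRS values, 3
secondary-structure probabilities (H, E, C), 2 exposure probabilities
(exposed, buried), 5 min-max-normalized amino-acid properties (steric
parameter, polarizability, volume, hydrophobicity, isoelectric point), and
a terminal flag. A prediction window spans 15 residues centred on the
target: $15 \times 34 = 510$ inputs. Window slots beyond a chain end are
all-zero with the terminal flag set to 1, which is also how the flag
resolves its meaning for chains short enough to overlap both termini.
SS/SA inputs normally come from an external predictor as probability
columns; one-hot true assignments can be substituted for ablations.

The classifier is a single-hidden-layer feed-forward network (sigmoidal
hidden units, softmax output, cross-entropy loss). The architecture and
hidden size (250) are the method's reference setting; the optimizer is
this package's choice and is recorded in the config: mini-batch SGD
(batch 128) with momentum 0.9, learning rate 0.01, at most 200 epochs,
early stopping after 10 epochs without validation-loss improvement,
returning the best-validation parameters. Weights initialize uniformly at
$\pm 1/\sqrt{\mathrm{fan\,in}}$ from the config seed; training is exactly
reproducible. Argmax ties break toward the earlier state in (R, I, F).

Cross-validation is seven-fold at **chain** level: a seeded shuffle
assigns whole chains to folds (sizes within one chain of each other); in
rotation $j$, fold $j$ validates, fold $j+1 \pmod 7$ tests, the rest
train. The fixed $(j, j+1)$ rule pins down which held-out subset plays
which role — the rotation scheme was otherwise open. Reported metrics are
per-state recall $Q_s$ (correct in $s$ / observed in $s$; "quality of
predicting state $s$" is read as recall, consistently with
$Q_3 = $ total correct/total) and their unweighted mean over folds. No
class re-weighting is applied by default.

## The synthetic test bed

The generator produces the study conditions for all tests: 200 chains of
40–120 residues by default (the length filter passes by construction).
Secondary structure alternates coil and regular segments (helix:strand
odds 0.6:0.4, geometric segment lengths); exposure is Bernoulli given the
segment class; the raw B-factor of a residue is a group baseline by
(SS, SA) — coil and exposed shifted upward — plus AR(1)-correlated
Gaussian noise ($\rho = 0.35$) plus an occasional lognormal spike
concentrated in exposed coil. The group means/SDs
(regular-buried 5 ± 1.2, regular-exposed 20 ± 2.5, coil-buried
21.5 ± 3, coil-exposed 23 ± 3.5, spikes $\sim 35 + $ heavy tail) were
calibrated once against the structural targets — right-skewed normalized
distribution, hotter coil than helix/strand, hotter exposed than buried,
and tails sized so all three states are populated in the proportions the
threshold design permits (roughly 0.2 / 0.75 / 0.04) — not against any
classifier outcome. Sequences carry SS-conditioned residue propensities
(boost 3), PSSM rows a +7 log-odds signal on the true residue over
integer noise (SD 2), and "predicted" SS/SA probabilities mix the truth
with uniform simplex noise at reliability 0.85, standing in for external
predictor output. A global `effect_scale` knob collapses every
flexibility-related difference at 0, giving an honest null model.

Because state is driven through (SS, SA), the conditional mode of the
state given the true (SS, SA) pair — tabulated on one sample, scored on
an independent one — is an achievable reference rate for any classifier
that sees the structural features; residual AR noise and spikes bound it
away from 1 (it sits near 0.88 under the defaults, reported by
`scripts/acceptance.R` at run time). The cross-validation recovery
threshold of 0.70 used in the tests was pinned beneath that oracle rate;
the tests additionally require the network to beat the majority-class
rate by a clear margin, which a constant classifier cannot.

What the synthetic bed does **not** establish: performance on real
corpora. Real PSSMs encode deep homology rather than an identity boost;
real SS/SA predictors have structured, not uniform, error; real B-factors
reflect crystal contacts, TLS refinement artefacts and dataset curation
that the generator does not model. Passing tests demonstrate that the
pipeline's machinery — labeling, statistics, encoding, training,
evaluation — is correct and recovers planted structure, not that the
accuracy figures transfer to real proteins.

## File-format decisions

PDB parsing is fixed-column (chain in column 22, B-factor in 61–66), not
whitespace-split; alternate locations resolve to the highest-occupancy CA
record with file order as the tie-break; only the first MODEL is read
unless another is requested; HETATM records are ignored and non-standard
ATOM residues become `X` (undetermined downstream). Coordinates are never
interpreted. PSI-BLAST ASCII PSSMs take the first 20 numeric columns (the
log-odds block) and ignore the percentage block. Potential tables,
checkpoints and reports serialize as structured JSON/TSV text; the corpus
writer rounds B-factors to the two decimals the PDB fixed-column format
can carry, so file round-trips are exact.

## Problem sizes

The test suite and the acceptance script run at sizes chosen for a
single-CPU desk machine: the default 200-chain corpus (~16k residues) for
the headline cross-validation with 64 hidden nodes and at most 40 epochs;
80-chain corpora with 32 hidden nodes for the five-seed feature ablation;
oracle-equivalence checks on corpora of at most 5 chains x 10 residues,
where exhaustive enumeration is feasible. The 250-hidden-node reference
configuration remains the default of `flex_net_config()`.

## Known limitations

* Doublet/triplet potentials are conditioned on the offset; pooling
  across offsets would trade resolution for density. The subscripted sum
  in the scoring formula motivated conditioning.
* The flexible class is rare by construction of the thresholds; its
  recall is the least stable metric at desk scale.
* Window widths other than 15 are configurable but not tuned.
* The CLI stages write/read their intermediates as TSV/JSON; very large
  corpora would want a binary container, which is out of scope.
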