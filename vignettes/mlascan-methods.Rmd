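---
title: "Methods: synthetic deep mutational scanning, interface mapping and 1:1 kinetics in mlascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic deep mutational scanning, interface mapping and 1:1 kinetics in mlascan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, what the synthetic-data generator
does and does not emulate, the numerical conventions, and the design
choices that were genuinely open.

## The estimator and the selection model

The mutational cost of variant $x$ at position $i$ is the wild-type-anchored
log enrichment across selection,

$$\Delta E_{ix} \;=\; \log\frac{f_{ix,\mathrm{sel}}}{f_{ix,\mathrm{unsel}}}
\;-\; \log\frac{f_{iWT,\mathrm{sel}}}{f_{iWT,\mathrm{unsel}}},$$

computed on counts-per-million frequency tables (`compute_fitness()`).
The natural log is the default; `log_base` is configurable because the
quantity is routinely reported in either base, and the selection rule below
is invariant to the choice (it rescales $\mu$ and $\sigma$ together.)
Anchoring to the wild type makes the score exactly invariant to uniform
rescaling of either condition's counts (sequencing depth), which the test
suite asserts to 1e-12.

The synthetic selection model is *multiplicative in* $\exp(\Delta E_\mathrm{true})$:
post-selection frequencies are pre-selection frequencies times
$e^{\Delta E_\mathrm{true}}$, renormalised, with the wild type carrying
$e^0 = 1$. This is a modelling choice, not a claim about bacterial growth on
selective plates: it is chosen precisely so that the log-ratio estimator is
the exact algebraic inverse of the selection, giving the pipeline a
closed-form round-trip identity (`compute_fitness(simulate_selection(f, T), f) = T`,
exact to floating point). The experiment's effective number of generations
is unknown, so the effect scale is arbitrary and only self-consistent;
nothing downstream depends on it because the selection rule is scale-free.

## What the generator emulates, and what it does not

`generate_nns_library()` enumerates the 32 NNS codons (N = any base,
S = G/C) at each of 211 positions; they cover all 20 amino acids plus one
stop (TAG), so each position contributes exactly 20 non-wild-type symbols
and the full library holds 4220 variants. The pool model is an equimolar
mixture of (position, codon) species: amino-acid variant frequencies are
proportional to their NNS codon multiplicities, and wild-type-synonymous
codons contribute wild-type molecules — as they do in a real NNS library.

Planted effects (`simulate_true_effects()`) are drawn hierarchically:
positions are assigned tolerant / intermediate / critical classes with
probabilities 0.6 / 0.2 / 0.2, and variant effects within a class come from
class-specific Gaussian mixtures (tolerant: $N(0, 0.3)$; intermediate:
half $N(0, 0.3)$, half $N(-2.5, 1)$; critical: 85% $N(-4.5, 1)$,
15% $N(-1, 0.7)$). Premature stops are fixed at $-6$ except in the last 10
positions, where truncation is tolerated. These choices were made once to
resemble saturation scans of essential-pathway proteins — a minority of
positions carrying many strongly deleterious mutations, nearly all effects
neutral-or-negative, and a fraction of functionally important positions
(classes put ~20% of positions in the critical class; the k/m rule selects
~27% of positions on the synthetic landscape, the scale observed for a
periplasmic carrier protein under envelope-stress selection).

`simulate_reads()` draws reads multinomially over codon species at a
default depth of 300× per variant — the middle of the several-hundred-fold
per-variant coverage regime of the emulated experiment — applies
substitution-only errors at a default 1e-3 per base, and emits half of the
reads as reverse complements so the counting stage must recover
orientation. Indels, quality scores, PCR bias, bottlenecking and colony
sampling are *not* modelled: the length filter would discard indel reads
anyway, and the remaining effects act as extra dispersion that the
synthetic data does not represent. Passing tests therefore demonstrate
correctness of the bookkeeping and the estimator under sampling and
substitution noise, not robustness to every artefact of a real sequencing
run. All generators take one explicit seed and restore the caller's RNG
state on exit.

A consequence of a 1e-3 error rate over a 321-nt amplicon is that ~20% of
reads acquire at least one extra amino-acid change and are discarded as
multi-mutants (the library is single-mutant by construction; decomposing
such reads would mis-assign errors to biology). This is visible in the
discard tallies and is a faithful cost of the stated error rate, mostly a
uniform depth loss. Wild-type reads with one error are counted as
single-mutant variants; at wild-type pool fractions of a few percent this
adds a small, uniform background.

## Counting conventions

Reads are filtered to the exact amplicon length; orientation is decided by
the smaller nucleotide Hamming distance to the wild-type amplicon over the
full read, with ties discarded as ambiguous; translation renders stops as
`*`. Reads with zero mismatches to the wild-type segment count toward the
wild type, exactly one mismatch increments that (position, symbol) cell,
two or more are discarded as multi-mutants. Read conservation
(`counted + wild type + discarded = input`) is asserted over 1000 random
fixtures. Sub-libraries are counted and normalised independently and their
landscapes concatenated by position, so each sub-library keeps its own
wild-type anchor; positions are 1-based on the full-length protein.

CPM normalisation adds a pseudocount (default 1 read) to every variant
cell and to the wild type before scaling to $10^6$. The emulated protocol
is silent on pseudocounts; default 1 prevents $\log 0$ for variants absent
from one condition, and `pseudocount = 0` is exposed, in which case
zero-frequency variants propagate as `NA` cells that are excluded from
means, SDs and qualifying-mutation counts.

## The selection rule

`select_functional_residues()` computes $\mu$ and $\sigma$ over all
observed mutation cells of the replicate-averaged landscape (stop variants
included — they are informative loss-of-function probes) and selects
positions with at least $k = 5$ mutations beyond $m = 1$ SD. Two
conventions were genuinely open:

* **Sidedness.** The default is one-sided ($\Delta E < \mu - m\sigma$):
  the screen detects loss of function and essentially no variants rise
  meaningfully above neutrality. `two_sided` is available and the analysis
  scripts report both.
* **SD flavour.** `sd()` (sample SD) is used, the field convention. On the
  60-cell hand-computable toy landscape the population SD gives exactly
  0.9 and the sample SD 0.9076; the selected set is identical.

A scale-free rule on a pure-noise landscape is *not* silent: with iid
Gaussian noise each position qualifies with probability
$P\{\mathrm{Binom}(20, \Phi(-1)) \ge 5\} \approx 0.20$, independent of the
noise amplitude. The suite tests this calibrated false-positive rate
rather than pretending the rule returns an empty set on neutral data; on
real landscapes the deleterious tail inflates $\sigma$ and suppresses the
false-positive rate well below this bound.

Group classification (signal peptide, lipid-binding pocket, buried,
surface) uses user-supplied annotations with precedence
signal peptide > pocket > buried > surface, since a pocket residue inside
an annotated range should not be double-counted.

## Interface mapping

Contacts use heavy atoms only (predicted models carry no hydrogens;
hydrogens are dropped on load, and alternate locations resolve to the
highest-occupancy conformer) and a *strict* inequality at the 4 Å cutoff.
The neighbour search bins atoms into a cubic grid of cell size equal to
the cutoff and compares only the 27 neighbouring cells; it is exact, and
the tests assert set equality with the all-pairs computation on hundreds
of random fixtures. Residue numbering offsets (e.g. +21 for a carrier
model built without its signal peptide) are applied at load time so that
footprints and DMS hits share full-length numbering; disjoint ranges in an
overlap computation trigger a warning, the usual symptom of a forgotten
offset.

Superposition is the Kabsch algorithm via SVD with the determinant
correction enforcing a proper rotation; the rotation angle is
$\arccos((\mathrm{tr}\,R - 1)/2)$. The angle is exquisitely accurate away
from the identity (a constructed 30° rotation is recovered to < 1e-6
degrees) but ill-conditioned *at* the identity, where only
$\mathcal{O}(\sqrt{\varepsilon})$ accuracy is achievable — the tests
encode both facts.

For carrier-on-ring complexes, models are superposed on the first via ring
C$\alpha$ atoms; pairwise carrier hinge angles are the rotation angles of
carrier-onto-carrier superpositions after ring alignment. The
inward/outward score is the distance of the carrier centroid to the ring
symmetry axis, taken as the principal axis of the ring C$\alpha$ cloud
with the *smallest* coordinate variance (the ring-plane normal) through
the ring centroid; the minimum-score model is labelled inward (closest to
the central transport tunnel) and the maximum outward. A pocket-entrance
based metric would be an alternative; the centroid metric needs no
annotation of the pocket and is monotone in the same geometry.

## 1:1 kinetics

The forward model and the fitted model are the same 1:1 Langmuir scheme:
association $R(t) = R_\mathrm{eq}\,(1 - e^{-(k_\mathrm{on} C + k_\mathrm{off}) t})$
with $R_\mathrm{eq} = R_\mathrm{max} C / (C + K_D)$, first-order
dissociation continuous at the phase boundary, $K_D = k_\mathrm{off}/k_\mathrm{on}$
by construction. The default schedule is baseline 60 s, association 30 s,
dissociation 100 s at 5 Hz — a standard fast-dissociation kinetics cycle —
and the default concentration series tops out at 100 µM, the ceiling used
for no-binding calls.

Fitting baseline-subtracts each trace (mean of the final 10 s of
baseline), shares $k_\mathrm{on}$, $k_\mathrm{off}$ and $R_\mathrm{max}$
across all concentrations of a sensor, and minimises joint
association+dissociation residuals by Levenberg–Marquardt in log-parameter
space with bounds $k_\mathrm{on} \in [10^2, 10^8]$ M$^{-1}$s$^{-1}$,
$k_\mathrm{off} \in [10^{-5}, 10]$ s$^{-1}$ and a 3×3 log-spaced
multi-start grid (the vendor software's settings are unpublished; the
multi-start makes the global fit insensitive to initialisation, which the
zero-noise round-trip tests confirm across random parameter draws).

The no-binding detector compares the *peak of the 1-s boxcar-smoothed*
association signal against 3× the baseline noise SD. Smoothing matters:
the raw maximum of several hundred iid noise points exceeds 3 SD in
expectation, so an unsmoothed peak criterion cannot call a flat trace
"none"; one second of smoothing restores the intended floor while leaving
a real binding plateau untouched. Classification against a wild-type
reference uses a KD fold-change threshold of 3 (diminished beyond it),
with "none" reserved for unfittable traces at the maximum concentration
tested. Mass-transport limitation, heterogeneous 2:1 schemes and avidity
of multivalent constructs are out of scope.

## Problem sizes and reproducibility

The study-scale synthetic experiment (211 positions, two sub-libraries,
two replicates, two conditions, 300× per-variant depth, 1e-3 errors —
about 5 million reads through the counting stage) runs in about two
minutes; the test suite uses reduced sizes for module tests and the full
scale for the end-to-end recovery check, where the planted-vs-estimated
Spearman correlation over $|\Delta E_\mathrm{true}| \le 5$ exceeds 0.98.
Every stochastic step takes an explicit seed; `run_pipeline()` stamps
outputs with a hash of the scientific configuration (paths excluded), and
identical configurations reproduce outputs byte for byte.

## Known limitations

* The effect scale of the synthetic selection is arbitrary (unknown
  generations); only rank structure and the scale-free selection rule
  transfer to real data.
* Validation against the deposited experimental score set and predicted
  complex models requires those files locally; the corresponding tests
  fail with instructions rather than silently passing when the deposits
  are absent.
* The naive paired-end merger is convenience plumbing (fixed-offset
  overlap, read-1 wins disagreements); real data should arrive pre-merged.
* The 4 Å contact criterion is convention-sensitive (atom subset,
  strictness, numbering); counts on deposited models can shift by a few
  residues under alternative conventions, so reports should state the
  convention (heavy atoms, strict 4 Å, full-length numbering) as the
  package does.
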