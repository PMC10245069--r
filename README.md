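# mlascan

Deep mutational scanning (DMS) and protein–protein interface analysis for
the bacterial Mla phospholipid transport pathway, centred on the
periplasmic lipid carrier MlaC of *Escherichia coli*.

MlaC shuttles phospholipids across the periplasm between the inner-membrane
MlaFEDB complex (via the hexameric MCE-domain ring of MlaD) and the
outer-membrane MlaA–OmpF/C complex. Mapping which MlaC residues matter — and
which of those sit at the MlaD and MlaA binding interfaces — requires three
kinds of computation that this package implements as one tested pipeline:

1. **Saturation-mutagenesis fitness scoring.** A pooled NNS library (N = any
   base, S = G/C; 32 codons covering 19 substitutions + stop at every
   position, 4220 variants over 211 residues, amplicon sub-libraries 1–107
   and 108–211) is selected for growth; merged amplicon reads are length
   filtered, oriented against the wild-type coding sequence, translated,
   and counted per (position, amino acid). Counts are normalised to reads
   per million, and each variant's mutational cost is

   ```
   ΔE_ix = log( f_ix,sel / f_ix,unsel ) − log( f_iWT,sel / f_iWT,unsel )
   ```

   the log enrichment of variant *x* at position *i* across selection,
   anchored to the wild-type enrichment (natural log; ΔE < 0 means loss of
   function). Replicates are averaged cell-wise, and functionally important
   residues are those at which ≥ k mutations (default 5) score more than
   m standard deviations (default 1) below the mean of all mutations.

2. **Interface mapping on predicted complex models.** Inter-chain residue
   contacts at a 4 Å heavy-atom cutoff (exact grid-accelerated search),
   interface footprints, overlap of footprints with DMS hits, Kabsch
   rigid-body superposition, pairwise hinge angles of a carrier bound to a
   ring, and inward/outward ranking by the distance of the carrier centroid
   to the ring symmetry axis.

3. **Binding kinetics.** Global 1:1 Langmuir fits of biolayer-interferometry
   sensorgrams (kon, koff, shared Rmax per sensor; KD = koff/kon), with
   wt-like / diminished / no-binding classification against a reference.

Every input has a synthetic twin with known ground truth: NNS libraries,
multiplicative selection (`post ∝ pre · exp(ΔE_true)`, the exact inverse of
the estimator), multinomially sampled reads with substitution errors and
random orientation, 1:1 sensorgrams, and toy two-chain complexes with
planted contacts. This makes every stage verifiable end to end without any
external download.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (about three minutes total):

```sh
Rscript analysis/01_simulate_library.R
Rscript analysis/02_fitness_landscape.R
Rscript analysis/03_functional_residues.R
Rscript analysis/04_interface_contacts.R
Rscript analysis/05_bli_kinetics.R
```

Stage 2 simulates the full experiment (2 replicates × 2 conditions ×
2 sub-libraries at 300× per-variant depth, 1e-3 per-base errors) and
prints:

```
planted vs estimated mutational cost (|true| <= 5, n = 3865): Spearman rho = 0.9859
selection rule (k = 5, m = 1, one-sided): mu = -0.9161, sigma = 1.5958, 58 residues selected
```

i.e. the estimator recovers the planted fitness effects nearly perfectly
at study-scale depth, and the k/m rule selects 58 of 211 positions — stage 3
confirms all 31 planted "critical" positions are among them. Stage 4 plants
a 5-pair interface in a toy complex and recovers exactly those 5 residue
pairs at 4 Å, and measures a constructed 21° carrier hinge rotation back to
two decimals. Stage 5 prints the kinetics fits and calls:

```
wild type:  KineticsParams: kon = 978.2 1/M/s, koff = 0.01819 1/s, KD = 1.859e-05 M, Rmax = 1.21 nm
10x mutant: KineticsParams: kon = 1078 1/M/s, koff = 0.1782 1/s, KD = 0.0001654 M, Rmax = 1.121 nm
WT      -> wt_like (fold change 1)
MUT10X  -> diminished (fold change 8.89)
NONE    -> none (fold change NA)
```

— a simulated KD of 18 µM is recovered within a few percent under 2% noise,
the 10×-weaker mutant is classified as diminished binding, and a flat trace
is called as no binding at the 100 µM maximum analyte concentration.

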