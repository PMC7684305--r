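---
title: "Methods: simulating and analysing foraminiferal sedaDNA metabarcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing foraminiferal sedaDNA metabarcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sedaforam)
```

This vignette is the package's own account of its methods: what each
component computes, which assumptions it makes, which parameters matter,
and where the design was genuinely open.

## The burial-decay model

Foraminiferal DNA in marine sediment has two sources. Benthic foraminifera
live in the bioturbated top of the core; their standing stock is modelled
as a linear decline from `B_surface = 99` (arbitrary units) at 0 cm to
`B_bottom = 1` at the bottom of the inhabited zone, `z_inhabited = 10` cm.
Planktonic eDNA arrives at the sediment surface with abundance `N0 = 1`
and decays exponentially with burial,

$$N(z) = N_0\, e^{-\lambda_p \tau z},$$

with decay constant `lambda_p = 1`. Below the inhabited zone benthic DNA
is purely environmental too and follows the same exponential form from its
boundary value (continuity at 10 cm), with a lower constant
`lambda_b = 0.9` — benthic DNA is buried with its cells and never transits
the water column, so it degrades less. The observable is the planktonic
amplicon fraction $P/(P+B)$.

Two modelling choices deserve comment:

* **The depth/decay-coordinate mapping.** The exponential form contains no
  explicit depth unit; the package makes the mapping explicit through
  `tau_scale` (model units per cm, default 0.02). With the stated
  abundance constants alone, no natural depth unit reproduces the observed
  ~96 % peak magnitude, so the package asserts the *shape* of the profile
  — surface fraction exactly $N_0/(N_0+B_\mathrm{surface}) = 0.01$, a
  maximum at the inhabited-zone bottom, and a strict decrease below it
  (guaranteed by $\lambda_b < \lambda_p$) — and treats the peak height as
  parameter-dependent. The default `tau_scale = 0.02` makes the fraction
  increase monotonically through the inhabited zone so the binned profile
  reproduces the low / peak / intermediate ordering of the three 10-cm
  reporting bins.
* **Whether `lambda_b = 0.9` is absolute or relative.** Both readings
  preserve the stated ordering; the package implements it as an absolute
  constant (0.9 versus 1.0).

`fit_decay_params()` estimates `(lambda_p, tau_scale)` by least squares on
the logit of the fraction, which respects the (0, 1) bounds. Both
parameters are identifiable when observations span both regimes, because
`tau_scale` also sets the benthic decay slope below the inhabited zone:
writing $a = \lambda_p \tau$ for the upper-zone slope and
$b = (\lambda_p - \lambda_b)\tau$ for the lower-zone slope of
$\log P/B$, the fixed $\lambda_b$ gives $\tau = (a - b)/\lambda_b$. The
lower-zone slope is small (0.002 per cm at the defaults), so under noise
`lambda_p` is the better-constrained of the two only through the
difference; estimates are bounded below at `lambda_b` to preserve the
model's ordering invariant, and fits that would cross the bound sit on it.
Non-convergence is reported as a flag, never an exception.

## The synthetic-data generator

`simulate_study()` emulates the structure of a multicore sediment survey
across a steep hydrographic front:

* **Taxon roster** (`default_taxa()`): nine planktonic morphospecies — a
  polar dominant, transitional and temperate species, three
  microperforates and one warm-advected species, plus the two spinose
  species — and 20 generic benthic taxa. Per-zone base abundances encode
  the polar (`LC`) / `transition` / temperate (`NAC`) gradient.
* **Amplification biases.** Taxa with `fwd_primer_mismatches >= 1` (the
  spinose clade; 1–3 mismatches in the forward-primer region) receive zero
  read mass: the dropout is deterministic, as total primer-site failure
  is. The temperate dominant carries a copy-number multiplier of 5,
  emulating rDNA over-representation; the value is illustrative, not
  estimated. The *G. uvula* analogue is enriched 10× in layers whose
  midpoint lies above 4 cm, mimicking a recent surface signal; the factor
  is a free knob because no quantitative value exists for it.
* **Communities.** A layer's expected read proportions put planktonic mass
  `fraction_profile(midpoint)` against benthic mass `1 − fraction`; within
  each habitat, zone-specific base abundances (times the biases) are
  renormalized. Layer depth is always the interval midpoint.
* **Reads.** Each sample unit (site × layer × PCR replicate, named
  `sample.rep1/2`) draws its reads multinomially and wraps each insert in
  the unit's tagged primers: 8-nt tags on both primers, combinations
  assigned on a cyclic Latin square, tag pools drawn with pairwise Hamming
  distance ≥ 5 so that 2-mismatch demultiplexing cannot be ambiguous.
  Mates overlap by construction; point errors are uniform substitutions;
  chimeras are single-breakpoint two-parent splices with
  abundance-weighted parents. Quality strings are constant Q37 — quality
  filtering is tested with separately injected low-quality reads, which
  keeps the error and quality models independent.
* **Census counts.** Microfossil censuses draw `n_tests` (default 250)
  planktonic tests multinomially from the *unbiased* zone assemblage — no
  primer dropout, no copy-number multiplier, spinose species present —
  plus benthic tests at a 100:1 planktonic:benthic shell ratio (Poisson).
  Census and eDNA assemblages therefore share an underlying composition
  and diverge only by the amplification biases, which is exactly the
  comparison the congruence analysis needs.

What the generator does *not* emulate: polymerase-specific error spectra,
PCR-cycle dynamics, fragment-length taphonomy, lateral advection, or
chronology. Passing tests demonstrate the pipeline's correctness and the
statistical machinery's calibration under these idealized conditions, not
performance on real sequencer output.

## The amplicon-processing chain

Stage order: quality filter → merge → demultiplex → chimera removal →
dereplication → assignment → pre-clustering → clustering → classification
→ occupancy filter. Chimera detection needs dataset-wide abundances, so
the runner dereplicates first and removes flagged units; read accounting
itemizes every drop so that assigned + unassigned + dropped equals raw at
every stage.

Numerical and boundary conventions, all configurable through
`pipeline_config()` and logged:

* *Quality*: a pair is kept iff **each** mate's mean Phred score is
  strictly above 30.
* *Merging*: largest exact suffix/prefix overlap ≥ 12 nt; no mismatches
  tolerated; no qualifying overlap rejects the pair.
* *Demultiplexing*: Hamming distance summed over the 5′ and 3′
  tag+primer constructs; assignment requires a unique minimum ≤ 2;
  equidistant ties are never guessed.
* *Alignment*: Needleman–Wunsch with match +1, mismatch −1, gap −2, end
  gaps penalized (the simplest classical scheme). Identity is matches
  divided by alignment columns, gap columns included. Among score-tied
  traceback moves the convention is diagonal, then gap in the second
  sequence, then gap in the first, making reported identities
  deterministic.
* *Assignment*: identity floor strictly above 0.80; tied best references
  vote and the deepest shared taxonomy prefix is returned.
* *Pre-clustering*: exact match of the first 30 bases (the 5′
  hypervariable signature). The published signature method is not fully
  specified, so the prefix length is a configuration knob.
* *Clustering*: average linkage on 1 − identity, cut at 0.03 (heights at
  or below the cut merge); per-pre-cluster overrides are keyed by taxonomy
  prefix because the original per-taxon thresholds are not enumerated
  anywhere. Members are processed in lexicographic order so distance ties
  resolve deterministically.
* *Classification*: planktonic iff best identity to a planktonic
  reference is ≥ 0.95 (inclusive boundary, recorded decision); everything
  else is benthic by exclusion, which mirrors how an almost-complete
  planktonic reference set is used in practice.
* *Occupancy*: OTUs kept when present in strictly more than 3 sample
  units.
* *Chimeras*: a simplified two-parent detector — parents at least twice
  the query's abundance, single-breakpoint splice, flag when the splice
  model reaches 0.99 identity and beats the best single parent. It is a
  deliberate simplification of reference-free chimera detection, adequate
  for splice-simulated data; it does not reproduce any published tool's
  scores.

## Community statistics

* **CSS normalization** implements the scaling step only: a sample's
  factor is the sum of its counts up to the chosen quantile (default
  0.5) of its nonzero counts, and normalized counts share a common scale
  of 1000. The zero-inflated Gaussian mixture sometimes fitted downstream
  of CSS belongs to differential-abundance testing, which this analysis
  does not perform. An optional adaptive mode picks the smallest quantile
  at which the across-sample spread of relative factors stabilizes.
* **Ordination** is classical scaling; when negative eigenvalues exceed
  tolerance the Cailliez additive correction is applied and recorded.
* **The dispersion test** embeds samples with negative-eigenvalue axes
  retained, computes each sample's distance to its group centroid
  (negative axes subtract, truncated at zero), and compares the one-way
  ANOVA F against label permutations with the +1 correction. The centroid
  (not the spatial median) is the recorded convention. The companion
  location test (`permanova_test()`) partitions squared distances among
  and within groups; both are provided and labelled because a bare
  "ANOVA on an ordination" can mean either, and they answer different
  questions.
* **Congruence** restricts fossil and molecular tables to shared samples,
  removes spinose taxa from the fossil side (the known dropout makes them
  uncomparable), converts to relative abundances, and reports per-source
  ordinations and tests plus a Mantel correlation between the two
  Bray–Curtis matrices. Census relative abundances are computed on
  planktonic tests only; benthic test counts are tracked separately.
* Permutation counts default to 999 with a mandatory seed; replicate
  handling defaults to summing the two PCR replicates before fractions
  (how the original replicates were averaged is not recorded, so the
  convention is explicit and switchable).

## Problem sizes

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes at which each property is informative: the
end-to-end study uses 4–6 sites × 10–15 two-centimetre layers × 2
replicates at 1000–2000 read pairs per unit (120 000–160 000 pairs);
oracle cross-checks use 200 alignment pairs and 1000 merge pairs;
calibration uses 300–500 null simulations at 199 permutations; parameter
recovery uses 30-point profiles with logit noise σ = 0.05 and 100
replicate fits.

## Known limitations

* The pipeline is exact-overlap and substitution-only: no quality
  trimming, no indel-aware merging, no denoising (no ASV model).
* Assignment aligns pairwise against each reference rather than against a
  multiple sequence alignment; with the short 37f region and a complete
  reference set the two agree in practice, but they are not identical
  procedures.
* The chimera detector is intentionally minimal (see above).
* The decay model is conceptual: it has no chronology, no bioturbation
  mixing, and no adsorption chemistry; only profile shape is asserted.
* The generator's defaults are the study conditions, not estimates; where
  the literature gives no value (surface-enrichment factor, copy-number
  multiplier, per-taxon clustering thresholds) the defaults are documented
  knobs.
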