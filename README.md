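# sedaforam

Sedimentary environmental DNA (sedaDNA) metabarcoding of planktonic
foraminifera: a tested, reusable implementation of the full analysis as an R
package plus a numbered analysis workflow.

## The scientific problem

Planktonic foraminifera live in the surface ocean; their calcite shells sink
and accumulate on the seafloor, where micropalaeontologists count them to
reconstruct past surface hydrography. Their DNA arrives on the seafloor too,
and persists after burial. Metabarcoding of the short 37f hypervariable
region of the SSU rRNA gene (68–196 bp) recovers both this planktonic eDNA
and DNA from benthic foraminifera living in the top ~10 cm of sediment. Two
questions follow: how does the planktonic:benthic amplicon ratio change with
burial depth, and does the buried molecular assemblage preserve the same
biogeographic signal as the co-occurring microfossils?

The package implements the four components needed to answer them without
any external data:

1. **A synthetic-study generator** (`simulate_study()`): taxonomy-annotated
   reference barcodes, depth- and zone-structured communities, tagged
   paired-end reads with a ground-truth table, and coupled microfossil
   census counts. The generator encodes the study conditions: spinose
   species dropped by forward-primer mismatches, a 5× rDNA copy-number
   multiplier for the temperate dominant, a 10× surface enrichment of a
   microperforate species above 4 cm, and two tagged PCR replicates per
   sample.
2. **The amplicon-processing chain** (`run_pipeline()`): per-mate mean
   Phred > 30 filter → exact-overlap merging (≥ 12 nt, no mismatches) →
   inline tagged-primer demultiplexing (≤ 2 construct mismatches, Latin
   square tag design) → two-parent chimera removal → dereplication to ISUs
   → Needleman–Wunsch taxonomic assignment (> 80 % identity floor,
   consensus of tied best hits) → 5′-signature pre-clustering →
   average-linkage OTU delineation (0.03 distance cut) → planktonic
   classification (≥ 95 % identity, benthic by exclusion) → retention of
   OTUs present in more than 3 samples.
3. **The burial-decay model** (`fraction_profile()`, `fit_decay_params()`):
   living benthic stock declining linearly from 99 to 1 (arbitrary units)
   over the inhabited zone (0–10 cm); planktonic eDNA decaying as
   *N(z) = N₀ e^(−λₚ τ z)*; benthic eDNA decaying below the inhabited zone
   at the lower rate λ_b = 0.9. The observable is the planktonic fraction
   *P/(P+B)*, which is 0.01 at the surface, peaks at the inhabited-zone
   bottom and decreases slowly below it.
4. **Community statistics** (`css_normalize()`, `bray_curtis()`,
   `pcoa_ord()`, `dispersion_test()`, `permanova_test()`,
   `congruence_report()`): cumulative sum scaling, Bray–Curtis
   dissimilarity, principal coordinates, permutation tests of dispersion
   and location, WARM-group aggregation of census counts, depth-binned
   planktonic-fraction profiles, and Mantel congruence between fossil and
   molecular distance structures.

## Worked example

The analysis workflow under `analysis/` runs the complete study:

```sh
Rscript analysis/01_simulate_study.R      # synthetic cores + census
Rscript analysis/02_process_reads.R       # the amplicon chain
Rscript analysis/03_decay_profiles.R      # decay model vs observed profile
Rscript analysis/04_community_comparison.R  # fossil vs molecular congruence
```

With the committed seed the workflow prints (abridged):

```
raw                    144000 reads   144000 units
demultiplexed          144000 reads   144000 units
otus_retained          144000 reads       27 units
  planktonic OTUs    : 7 - Globigerinita_glutinata, Globigerinita_uvula,
                       Globorotalia_hirsuta, Globorotalia_inflata,
                       Neogloboquadrina_incompta, Neogloboquadrina_pachyderma,
                       Tenuitella_fleisheri
  spinose taxa absent : TRUE

     bin mean_fraction n_samples
  [0,10)     0.0266250        30
 [10,20)     0.4468333        30
 [20,30)     0.4417708        30

Zone contrasts (permanova p): census = 0.001 | molecular = 0.001
Mantel correlation census vs molecular: r = 0.912 p = 0.001
```

Reading: the no-noise run resolves exactly one OTU per amplifiable taxon
(7 planktonic + 20 benthic); the two spinose species are absent from the
molecular assemblage although present in the census, reproducing the
primer-dropout bias; the depth-binned planktonic read fraction is low in
the bioturbated top 10 cm, peaks between 10 and 20 cm and stays above the
surface value below 20 cm, as the decay model predicts; and the fossil and
molecular ordinations carry the same zone signal (both permutation ANOVAs
significant, Mantel r ≈ 0.9).

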