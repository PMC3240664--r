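# interbandscope

Interval genomics of interband-like open chromatin in *Drosophila*.

Polytene-chromosome interbands are short (~1–4 kb) decompacted chromatin
regions; thirteen of them have been mapped to the base pair via P-transposon
insertion anchors (distributed 1:3:4:5 over chr2R, chr3L, chr3R, chrX).
`interbandscope` implements, as a tested reusable pipeline, the analysis that
characterizes such regions in cell-line chromatin:

* **Anchored window profiling** — bound/unbound calls per region, 0.5-kb
  segment heat-maps over 10-kb windows, per-class profiles, chromatin-state
  composition and state-enrichment ratios around anchors.
* **Resampling enrichment test** — 13000 chromosome-weighted random chunks
  give an empirical per-region overlap frequency `p`; significance for the
  observed count `m` of bound anchors is the binomial tail
  `P(p, m, 13) = Σ_{i=0..m} C(13,i) p^i (1-p)^(13-i)`, with the published
  observed-tail rule (`P' = 1 − P` when `m > 13p`) and star bins at
  1e-2 / 1e-3 / 1e-6. Genome-wide and band-control backgrounds.
* **Fragment length classes** — per-protein counts and one-decimal
  percentages in the 1–3 / 4–6 / 7–9 / 10–11 kb classes.
* **Co-localization** — the similarity rate `r_ij = k / min(m′, n′)` after
  mutual redundancy removal (maximum bipartite matching on the
  interval-overlap graph), plus a 2×2 chi-square over non-overlapping 3-kb
  genome blocks (`n = 40000` at the 120 Mb reference scale, expected
  co-occupancy `en = l·m/n`).
* **Embedding & clustering** — ordinal (non-metric) 2-D MDS and average
  linkage agglomerative clustering of `d = 1 − r`.
* **Synthetic data** — a generator that plants interband-like loci, active
  vs. silent protein groups, anchors and a RED-analog state map, so the whole
  pipeline runs and is verified without downloads.

All interval containers are Bioconductor `GRanges`; IO covers GFF2/3, BED,
TSV genome/anchor tables and BED-like state maps.

## Worked example

```r
library(interbandscope)
w  <- generate_world(sim_config(seed = 1))   # 12 Mb world, 350 planted loci
er <- enrichment_report(w$tracks[c("CHRIZ", "WDS", "PC", "SU(HW)")],
                        w$anchors, w$genome, seed = 1)
er[er$window_bp == 10000, c("protein", "m", "pct_bound", "p",
                            "P_final", "direction", "stars")]
#>  protein  m pct_bound     p P_final direction stars
#>    CHRIZ 13     100.0 0.451  0.0000  enriched   ***
#>      WDS 13     100.0 0.474  0.0000  enriched   ***
#>       PC  2      15.4 0.351  0.1120  depleted      
#>   SU(HW)  1       7.7 0.322  0.0459  depleted      
```

Both planted "active" proteins bind all 13 anchor regions (`m = 13`, 100%)
while random 10-kb chunks hit them only ~45–47% of the time, giving
`P' < 1e-6` (`***`, enriched); the Polycomb-group and insulator tracks sit
at or below their random expectation (depleted, no stars).

```r
round(similarity_matrix(w$tracks[c("CHRIZ", "WDS", "ORC2", "PC", "E(Z)")],
                        prepare = TRUE), 2)
#>       CHRIZ  WDS ORC2   PC E(Z)
#> CHRIZ  1.00 0.65 0.66 0.07 0.07
#> WDS    0.65 1.00 0.64 0.06 0.08
#> ORC2   0.66 0.64 1.00 0.05 0.08
#> PC     0.07 0.06 0.05 1.00 0.13
#> E(Z)   0.07 0.08 0.08 0.13 1.00

groups(to_dissimilarity(similarity_matrix(w$tracks, prepare = TRUE)), k = 2)
#>     CHRIZ  RNApolII   BEAF-32       WDS      ORC2       TRX        PC 
#>         1         1         1         1         1         1         2 
#>      E(Z)     dRING    SU(HW) MOD(MDG4)      CTCF 
#>         2         2         2         2         2
```

Active proteins co-localize (`r ≈ 0.65` within group vs. `≈ 0.07` across)
and the dendrogram cut at two groups recovers the planted active/silent
split exactly.

End-to-end runs (simulate → profile → enrich → lengths → coloc → cluster,
TSV outputs plus a JSON manifest with seeds and md5 hashes):

```r
run_all(list(seed = 1, outdir = "out",
             simulate = list(n_loci = 60,
                             genome = list(arm = c("chr2R","chr3L","chr3R","chrX"),
                                           length = rep(9e5, 4)))))
```

or from the shell via the installed CLI:

```sh
ibs=$(Rscript -e 'cat(system.file("exec/interband-scope", package="interbandscope"))')
Rscript "$ibs" simulate --config cfg.json --outdir out/sim --seed 3
Rscript "$ibs" validate --genome out/sim/genome.tsv --track CHRIZ=out/sim/track_CHRIZ.bed
```

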