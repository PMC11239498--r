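# epiremod

Quantitative machinery for studying multiscale epigenome remodeling
during transcription-factor-driven cell-fate conversion (e.g. proneural
bHLH factors reprogramming astrocytes into induced neurons). The package
re-implements, as tested and reusable R functions, the analysis layer
that sits between standard preprocessing and biological interpretation:

- **Enhancer–gene pair (EGP) linking** from paired single-cell
  ATAC + RNA (multiome) data: QC filtering, metacell aggregation,
  candidate pairing of distal peaks with genes separated by 5–500 kb,
  Pearson correlation of log-normalized metacell profiles, an empirical
  null from GC- and accessibility-matched background peaks
  (`p = (1 + #{|r_null| >= |r|}) / (n_bg + 1)`), Benjamini–Hochberg FDR,
  and classification into positive (`r > 0.35, q < 0.1`), negative
  (`r < -0.35, q < 0.1`) and non-correlated links.
- **TF target scoring**: the per-gene linkage score
  `L = sum_i r_i^2` over TF-evidenced links (a promoter hit counts as
  `r = 1`), with exact hypergeometric enrichment of TF evidence against
  matched background peaks.
- **Hi-C feature statistics**: read-pair filtering (mapq > 30, same
  fragment, < 1 kb), iterative-correction balancing, contact probability
  `P(s)` with power-law slope recovery, A/B compartments from the
  dominant eigenvector of the obs/exp correlation matrix with
  compartment strength over >= 10 Mb pairs, insulation-score TAD boundary
  calling, rescaled average TAD enrichment, aggregate contact analysis
  (APA) at anchor pairs, and per-pair 10-kb window contact scores.
- **CpG methylation**: context/coverage filtering (CpG context, >= 10x),
  per-region mean levels and feature-centered average profiles.
- **Peak-set analytics**: overlap partitioning of two ChIP universes,
  promoter/distal annotation, motif counting and enrichment (E-box
  `CAGATG` by default), covariate-matched background sampling,
  DEG-window overlap fractions.
- **A synthetic-data module** that generates every input with planted
  ground truth (power-law contact maps with A/B checkerboard, TADs and
  loop anchors; multiome matrices with planted peak–gene correlations;
  methylomes with hypomethylated dips; two-condition ChIP universes with
  planted motif copies), so every downstream statistic is testable
  without external data.

## Worked example

```r
library(epiremod)

cfg <- sim_config(seed = 101, n_cells = 5000, n_peaks = 2000,
                  n_genes = 200, n_linked = 50, rho = 0.7)
mo    <- gen_multiome(cfg)
kept  <- filter_cells_qc(mo$qc)
mc    <- make_metacells(mo$atac[kept, ], mo$rna[kept, ], k = 50, seed = 101)
prs   <- candidate_pairs(mo$peaks, mo$genes)          # 5 kb <= d <= 500 kb
links <- classify_links(correlate_and_test(mc, prs, mo$peaks,
                                           n_bg = 100, seed = 101))
planted <- paste(links$peak_id, links$gene_id) %in%
  paste(mo$truth$linked_pairs$peak_id, mo$truth$linked_pairs$gene_id)
mean(links$r[planted])                   #> 0.7076399
mean(links$class[planted] == "positive") #> 1
table(links$class)[["positive"]]         #> 51
nrow(prs)                                #> 350
```

All 50 planted links (true correlation 0.7) are recovered as positive
EGPs at `q < 0.1`, with the measured metacell correlation (0.708) close
to the planted value; of the ~300 distance-eligible but unlinked
candidate pairs, one borderline false positive sneaks in (empirical FDR
1/51, well under the 0.15 the sampling noise allows).

Hi-C side, from the same seeded world:

```r
g  <- gen_contact_map(sim_config(seed = 301, compartment_multiplier = 1.5))
cp <- compartments(g$matrix,
                   orientation_track = as.numeric(g$truth$compartment_labels == "A"))
mean(cp$labels == g$truth$compartment_labels, na.rm = TRUE)  #> 1
cp$strength                                                  #> 1.655302
```

The eigenvector sign recovers the planted checkerboard on every bin;
the within/between obs-exp strength (1.66 > 1) rises monotonically with
the planted multiplier (1.25 / 1.66 / 2.27 across multipliers
1.2 / 1.5 / 2.0 in the test suite) while a structureless control stays
at 1 within 0.1 log2 units.

## End-to-end run

`run_pipeline(run_config(outdir, seed))` executes
simulate → QC/metacells → links → target scores, plus the Hi-C and
methylation branches, writing plain-text tables and a `manifest.json`
with config hash and per-file checksums (identical config + seed gives
byte-identical outputs).

`scripts/acceptance.R` re-runs that complete pipeline from scratch under
a caller-supplied seed:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It executes every stage on the synthetic world and writes the
result-summary JSON to `--out`.

## Vignette

`vignettes/epiremod-methods.Rmd` describes the statistical models, the
defaults and their rationale, what the synthetic generator does and does
not emulate, and known limitations.
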