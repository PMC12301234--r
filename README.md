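# panscreen

In-silico clone selection for antibody phage-display discovery campaigns.

Synthetic VHH (single-domain antibody) libraries panned against an antigen
over several selection rounds produce deep-sequencing output from which
binder candidates must be triaged — by round-to-round clonotype enrichment
and by machine-learning classifiers trained on limited binding data. That
triage logic is hard to validate on real campaigns because ground truth
(which clones truly bind, which sequences carry liabilities) is unknown.
panscreen provides the full computational pipeline *plus* a generative model
with known ground truth, so every stage is testable end to end:

* **Simulation** — combinatorial fixed-framework VHH libraries with
  liability-free CDRs, planted liability motifs, planted binder motifs, and
  multi-round panning under a Langmuir selection model: clone weight
  `w = n · (C/(C + K_D) + r)` at antigen concentration `C` with wash
  retention `r`, resampled multinomially at fixed sequencing depth.
  Per-round FASTQ output with substitution errors.
* **Repertoire** — anchor-based read orientation (both strands),
  translation, framework/CDR annotation with fuzzy matching, ELISA hit
  calling (inclusive ≥3-fold over background with a floor), dereplication.
* **Liability screen** — PTM motifs (deamidation N[GST], isomerization
  D[GST], glycosylation sequon N[^P][ST], unpaired CDR cysteines,
  pyroglutamate precursor), cryptic splice consensus sites, and restriction
  sites (SfiI by default), with a category-based removal policy.
* **Enrichment** — exact-CDR3 clonotypes, pseudocount-regularized log2
  frequency ratios between rounds 3 and 4
  (`log2((f4 + p4)/(f3 + p3))`, `p_r = pseudocount/N_r`), top-clonotype /
  top-3-variant candidate selection, provenance-tracked aggregation.
* **ML triage** — (1) descriptor → z-score → PCA → KNN with F-beta-tuned
  hyperparameters; (2) a one-hot convolutional sequence classifier
  (conv → global max pool → dense → sigmoid, mini-batch Adam, checkpoint
  selected on validation F1), probability thresholding, and k-medoids
  diversification on normalized edit distance.
* **Assay analyses** — SPR cross-competition epitope binning (threshold →
  OR-symmetrization → identical-pattern bins), hydroxyl-radical
  footprinting protection calls (modification fractions, signed percent
  fold-change, pooled-variance Student's t), and tumor growth inhibition,
  `TGI = [1 − (Tt − T0)/(Ct − C0)] × 100%`.

See `vignettes/panning-triage-methods.Rmd` for the models, defaults, and
limitations.

## Worked example

```r
library(panscreen)

design   <- vhh_library_design(pool_sizes = c(20, 20, 40),
                               liability_fraction = 0.1, seed = 1)
campaign <- generate_library(design, n_clones = 500)
campaign <- assign_affinities(campaign, binder_fraction = 0.1,
                              binder_motif = "WGWG", seed = 2)
campaign <- simulate_panning(campaign, panning_config(reads_per_round = 20000,
                                                      seed = 3))
campaign
#> <panning_campaign> 500 clones; 4 rounds simulated at depth 20000
#>   binders: 57
#>   planted liabilities: 50
```

The liability screen removes exactly the planted clones — the generator
guarantees that unplanted clones are motif-free:

```r
screened <- filter_library(campaign$clones)
nrow(screened$removed)
#> [1] 50
```

Clonotype enrichment from round 3 to round 4 ranks binders first:

```r
v  <- tibble::tibble(aa = campaign$clones$aa, cdr3 = campaign$clones$cdr3,
                     count_r3 = campaign$counts[, "R3"],
                     count_r4 = campaign$counts[, "R4"])
ct <- assign_clonotypes(v)
head(enrichment_table(ct$clonotypes), 3)
#> # A tibble: 3 × 5
#>   clonotype_id cdr3         freq_r3 freq_r4 enrichment
#>   <chr>        <chr>          <dbl>   <dbl>      <dbl>
#> 1 CT00033      SYALWGWGLPGA  0.0156  0.0187      0.261
#> 2 CT00002      EYKSMYWGWGYT  0.0398  0.0476      0.256
#> 3 CT00013      LPKIHWGWGRLQ  0.0209  0.0250      0.255
```

The top clonotypes carry the planted binder motif (`WGWG`) in CDR3. ML
triage recovers binder labels on held-out clones:

```r
spr      <- simulate_spr_labels(campaign, 100, seed = 4)
training <- build_training_set(spr, library_sample = campaign$clones$aa,
                               neg_sample_size = 100, seed = 5)
knn <- tune_knn(training, seed = 6)
knn
#> <knn_triage> components = 15  k = 7  (CV F1 = 0.804)
held  <- setdiff(campaign$clones$aa, training$aa)
truth <- campaign$clones$is_binder[match(held, campaign$clones$aa)]
balanced_accuracy(truth, predict(knn, held))
#> [1] 0.897
```

Assay-side analyses are one-liners:

```r
footprint_test(c(0.10, 0.11, 0.09, 0.10), c(0.20, 0.21, 0.19, 0.20))
#>   mean_bound mean_unbound log2_fc percent_fc     t    df       p      call
#> 1        0.1          0.2      -1        -50 -17.3     6 2.37e-06 protected
compute_tgi(100, 550, 100, 1000)
#> [1] 50
```

The full pipeline — simulate → annotate → screen → enrich → triage →
aggregate — runs from one seeded configuration (`run_config()` +
`run_pipeline()`), writes a manifest with per-stage accounting and file
checksums, and is byte-reproducible per seed. A thin CLI wrapper lives at
`inst/scripts/panscreen`.

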