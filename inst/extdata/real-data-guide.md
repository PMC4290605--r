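# Plugging in the real dataset

The published performance figures for this method — 5-fold CV MCC 0.66,
sensitivity 73%, specificity 98%, accuracy 97%, AUC 0.91, and the
93-feature optimum with its merit scores — were measured on a curated
experimental sumoylation dataset (357 positive / 7,909 negative training
sites in 233 proteins, plus an independent 534-site test set) together
with per-residue conformational-flexibility and disorder predictions from
external tools (FlexPred with PSSM-based encoding; IUPred). None of those
inputs ship with this package, so those exact numbers are **not**
reproducible from the package alone; the test suite replaces them with
property-based checks on synthetic data that plants the same reported
effect sizes.

To attempt a full reproduction, supply:

1. **Protein sequences** — a FASTA file; the first whitespace-delimited
   header token is the protein id (`read_fasta()`).
2. **Site labels** — a TSV with columns `protein_id`, `position`
   (1-based lysine position), `label` (`positive`/`negative`);
   `#` lines are comments (`read_site_labels()`).
3. **Flexibility/disorder annotations** — a TSV with columns
   `protein_id`, `position`, `flexible` (0/1, from a conformational
   flexibility predictor), `disorder` (tendency in [0,1], from a disorder
   predictor), one row per residue, covering at least every labeled
   lysine (`read_annotations()`). Without them, `null_annotations()`
   runs the pipeline with those three features switched off
   (all-zero), mirroring the published ablation.

Then point a pipeline configuration at the three files:

```r
cfg <- default_config()
cfg$paths$fasta       <- "proteins.fasta"
cfg$paths$sites       <- "sites.tsv"
cfg$paths$annotations <- "annotations.tsv"
cfg$paths$out_dir     <- "real_run"
run_pipeline(cfg, "encode")
run_pipeline(cfg, "select")    # ReliefF ranking + feature-count curve
run_pipeline(cfg, "train")     # grid search + final weighted RBF-SVM
run_pipeline(cfg, "evaluate")  # CV, self-consistency, regex baseline
run_pipeline(cfg, "stats")     # chi-square / Mann-Whitney screening
```

Expect the full grid search (21 x 19 points, 10-fold CV) and the
137-step selection curve to be compute-intensive at the real dataset's
size; `config$svm$grid$step` and `config$selection$stride` coarsen both.
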