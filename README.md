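# sedadiv

Replicate-aware quality control and diversity analysis for sedimentary
ancient DNA (sedaDNA) metabarcoding.

## The problem

Plant metabarcoding of dated lake-sediment cores reconstructs past
vegetation: each sediment sample yields amplicon sequences of a short
chloroplast barcode (the trnL p6-loop), amplified in eight independent
PCR replicates per DNA extract. Replication is the evidence base — a
sequence present in most replicates is real; one appearing sporadically
behaves like the contamination seen in negative controls. Multi-lake,
multi-millennium studies need sample-level quality control that is
objective and comparable across sites before any ecology can be read
from the data.

sedadiv implements that full chain for analysts working with
per-replicate read-count tables:

* **Quality scores.** MTQ (metabarcoding technical quality) and MAQ
  (analytical quality): the proportion of positive replicate detections
  among a sample's ten most read-abundant sequences — before taxonomic
  identification (MTQ) or after identification and false-positive
  removal (MAQ) — out of 80 possible detections. Samples pass QC iff
  MTQ ≥ 0.75 and MAQ ≥ 0.2; negative controls fail this gate.
* **Filtering and harmonization.** Per-replicate removal of cells with
  ≤ 2 reads, exact-match taxonomy against a curated reference database,
  blacklist removal, a dataset-wide ≥ 10 reads / ≥ 3 replicate-cells
  rarity filter, merging of co-occurring same-taxon barcodes (reads
  summed, replicate detections unioned), and exclusion of aquatic,
  algal and above-family taxa.
* **Detectability-weighted diversity.** Per-taxon detectability weights
  replicates by their share of the sample's retained reads (wtRep),
  falling back to plain replicate proportions in sparse samples; Hill
  numbers N0 (richness) and N1 = exp(−Σ pᵢ log pᵢ) (effective common
  taxa); analytic rarefaction; accumulated richness through time.
* **Regional species pool.** Taxon accumulation across all lakes with
  piecewise growth rates, and 500-year-binned pool estimation: Beals
  co-occurrence smoothing bᵢⱼ = (1/Sᵢ′) Σₖ Mⱼₖ/Nₖ with per-taxon
  minimum-observed-probability thresholds, then standardization by 1000
  resamples of 5 samples per bin.
* **Drivers.** A catchment nutrient index NI = (P + K + ln Ca)/H_min;
  nearest-age climate-proxy (δ¹⁸O) assignment; Holocene period splits
  (Early 11.7–8.3 ka, Middle 8.3–4.25 ka, Late 4.25–0 ka); per-lake and
  regional Poisson GAM/GAMM richness trends with optional CAR1
  residuals; and a linear mixed model of log richness on
  period-specific climate and nutrient slopes with per-lake random
  intercepts and age slopes.
* **Synthetic data.** A ten-lake study generator with replicate
  dropout, contaminants, blacklist hits and negative controls, used by
  the test suite for oracle checks and parameter-recovery studies.

## Worked example

Simulate a small four-lake study and run the pipeline end to end:

```r
library(sedadiv)

cfg <- simulation_config(
  n_lakes = 4, samples_per_lake = c(12, 18), pool_size = 150,
  colonization_rate_curve = data.frame(
    old = c(11700, 7000, 5000, 3300), young = c(7000, 5000, 3300, 0),
    rate = c(16, 4, 8, 2)),
  seed = 2024)
ds <- simulate_dataset(cfg, out_dir = "fixture")

run <- run_pipeline(pipeline_config(
  counts = ds$paths[["counts"]],
  reference_fasta = ds$paths[["reference_fasta"]],
  taxonomy = ds$paths[["taxonomy"]],
  blacklist_synthetic = ds$paths[["blacklist_synthetic"]],
  blacklist_false_positive = ds$paths[["blacklist_false_positive"]],
  lakes = ds$paths[["lakes"]], samples = ds$paths[["samples"]],
  proxy = ds$paths[["proxy"]], out_dir = "out",
  n_resamples = 300, seed = 5))

head(run$qc[, c("sample_id", "sample_type", "mtq", "maq", "passed")], 4)
#>   sample_id sample_type    mtq    maq passed
#> 1  L01_nc02 neg_control 0.0375 0.0375  FALSE
#> 2  L01_s001      sample 0.8750 0.9500   TRUE
#> 3  L01_s001      sample 0.9500 0.9500   TRUE
#> 4  L01_s002      sample 0.8875 0.9625   TRUE
```

56 of 58 samples pass the gate; all 6 negative controls fail it (their
best sequences replicate in ~3 of 80 possible detections). Sample
`L01_s001` appears twice because it was extracted twice; the extract
with the higher MAQ is retained. Downstream tables:

```r
head(run$diversity[, c("sample_id", "age", "n0", "n1", "rarefied", "mode")], 4)
#>   sample_id   age n0    n1 rarefied     mode
#> 1  L01_s001 11528 17 15.42       17 weighted
#> 2  L01_s002 10458 28 27.85       28 weighted
#> 3  L01_s003 10439 17 16.89       17 weighted
#> 4  L01_s004  9938 24 23.80       24 weighted

run$driver_fit$slopes_d18o
#>   period estimate     se df  lower upper  p_value
#> 1  Early    0.268 0.0339 45  0.199 0.336 4.89e-10
#> 2 Middle   -0.102 0.2624 45 -0.631 0.427 7.00e-01
#> 3   Late    0.335 0.2803 45 -0.230 0.899 2.39e-01
```

`n0` is taxon richness per sample, `n1` the effective number of common
taxa (≤ n0 by construction), `rarefied` the expected richness at the
lake's minimum read depth, and `mode` records whether wtRep or the
plain replicate proportion was used. The driver-model slopes recover
the structure this simulation was built with — a positive
climate–richness relationship confined to the Early Holocene (true
slope 0.24 per δ¹⁸O unit) — with the Middle/Late intervals straddling
zero. The regional accumulation curve reaches 114 taxa, and the binned
species pool grows with time (quadratic fit, adjusted R² = 0.99 on this
small fixture).

All stage outputs are also written as TSV under `out/` (QC report,
harmonized taxon table, diversity, accumulation curves, species-pool
bins, trend curves, driver-model summary) along with a `run_log.txt`
that echoes thresholds, seed and per-stage record counts. Reruns with
the same configuration are byte-identical.

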