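# mbsparse

Deep-learning imputation of non-biological zeros in microbiome count
matrices, with the corruption/benchmark protocols needed to test recovery
on synthetic data.

Taxonomic profiles from 16S or shotgun metagenomic sequencing are dominated
by zeros — often 70–90% of entries — and those zeros mix genuine absences
(*biological zeros*) with artifacts of limited sequencing depth and
technical bias (*non-biological zeros*). mbsparse fills likely
non-biological zeros by borrowing information from similar samples, without
assuming any predefined count distribution, and **never alters an observed
non-zero count**. It is aimed at microbiome researchers who want a
zero-aware preprocessing step before differential-abundance testing,
classification, or correlation analyses.

## Method

For a counts matrix `M` (n samples × m taxa), the pipeline works on
`X = log10(M' + 1)` where `M'` is `M` total-sum-scaled to 10⁶ reads per
sample:

1. a **feature autoencoder** (m → 512 → 128 → 512 → m, trained on
   reconstruction MSE) yields a per-sample embedding `Z`;
2. a directed **KNN sample-correlation graph** connects each sample to its
   k = 5 Euclidean nearest neighbours `N_i` in embedding space;
3. a **conditional VAE** trained over graph edges on the ELBO learns
   `p(X_u | X_v)` and generates one conditional sample `X^c_v` per node
   from a prior latent draw;
4. every zero entry is filled by averaging real and conditional neighbours,

   `X_ij ← (1 / 2K) Σ_{r ∈ N_i} (X_rj + X^c_rj),  K = |N_i|,`

   while non-zero entries pass through bit-exact. A zero whose neighbours
   are all zero stays zero, which is how putative biological zeros survive.

Ablation variants (`no_fae`, `no_cvae`, `neither`) are first-class pipeline
modes. The package also ships a zero-inflated low-rank synthetic count
generator, corruption protocols (dropout injection, multinomial depth
downsampling, outlier-sample construction, zero-free submatrix extraction)
and evaluation statistics (masked MSE, per-taxon Pearson/Spearman,
identification rate of injected zeros, standard-major-axis regression).
See `vignettes/mbsparse-methods.Rmd` for the full model description and
design rationale.

## Worked example

Corrupt a synthetic matrix, impute it, and score the recovery:

```r
library(mbsparse)
spec <- synthetic_spec()          # 100 samples x 300 taxa, 30% zero inflation
complete <- synthesize_count_matrix(spec)
exper <- inject_dropout(complete, rate = 0.2, seed = 42)
config <- mbsparse_config(seed = 42,
                          fae = fae_config(hidden_dim = 128, embedding_dim = 32, epochs = 80),
                          cvae = cvae_config(hidden_dim = 128, epochs = 80))
result <- run_mbsparse(exper$corrupted, config)
result
#> mbsparse_result: 100 x 300; 13150 of 13150 zeros filled (100.0%)
#>   variant: full, k = 5, seed = 42
recovery_report(exper, result)
#> evaluation_report (logged scale, 4212 masked entries):
#>   masked MSE        3.0720 (non-imputed 11.4644)
#>   identification    100.00%
#>   mean Pearson      0.6997 (non-imputed 0.7449)
#>   mean Spearman     0.7237 (non-imputed 0.7599; 0 taxa excluded)
```

Reading the numbers: imputation cut the squared error at the deliberately
zeroed coordinates from 11.46 to 3.07 (logged scale) and restored 100% of
the injected zeros to non-zero values. The per-taxon correlations of this
synthetic benchmark sit slightly below the non-imputed baseline — an
expected consequence of averaging neighbour values that include zeros under
the generator's unstructured zero inflation; the methods vignette discusses
why, and why structured (real-data-like) zeros behave differently.

On real data: `read_count_matrix("counts.tsv")` (TSV/CSV or BIOM; samples
as rows or taxa as rows via `orientation=`), then `run_mbsparse()` with the
default configuration. `result$imputed_logged` and
`result$imputed_normalized` hold the output on the two scales;
`plot_training()` and `plot_recovery()` give quick diagnostics. A thin
command-line wrapper with `impute` / `simulate` / `corrupt` / `evaluate` /
`experiment` subcommands lives at `inst/cli/mbsparse.R`.

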