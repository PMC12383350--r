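# perturbOT

Single-cell perturbation response prediction from **unpaired**
control/stimulated scRNA-seq data, with out-of-sample generalization to
held-out cell types.

## The problem

scRNA-seq destroys cells on measurement: a perturbation experiment observes
*different* cells under control and stimulation, never the same cell twice.
Given control profiles of a cell type whose stimulated state was never
measured (or never seen during training), perturbOT predicts what those
cells would look like after the perturbation — e.g. predicting the
interferon-stimulated state of held-out CD4 T cells from PBMC data where all
other types were observed under both conditions.

## The method

Cells are rows, genes are columns, expression is log1p of counts-per-10k
over highly variable genes. Three stages:

1. **MMD-regularized VAE.** An MLP encoder/decoder pair learns a latent
   space; the training objective is

   `L = mean_i ||x_i − x̂_i||² + α · MMD²({z_i}, {z_prior})`

   with `z = μ + ε ⊙ σ` (reparameterization trick) and the squared maximum
   mean discrepancy estimated by the biased V-statistic under a Gaussian RBF
   kernel `k(x,y) = exp(−||x−y||²/2σ_b²)`. A closed-form KL arm
   (`regularizer = "kl"`) is kept for ablation.

2. **Exact optimal transport.** The latent control and stimulated training
   populations are aligned by exact earth mover's distance under uniform
   marginals (cost `C_ij = ||z_i^ctrl − z_j^stim||²`; transportation simplex
   in C++). Each training control cell gets a perturbation delta by
   barycentric projection of the coupling:
   `Δ_i = (Σ_j γ_ij z_j^stim)/(Σ_j γ_ij) − z_i^ctrl`.

3. **Similarity-weighted transfer.** A held-out control cell receives the
   convex combination of the deltas of its `top_k` most cosine-similar
   training control cells, is shifted in latent space, and decoded:
   `x̂ = Decoder(z_test + Δ_pred)`.

Evaluation follows the standard unpaired protocol: squared Pearson R² of
gene-wise means (and variances) between predicted and observed stimulated
cells, a Fisher-z 95% CI on the mean regression, and the overlap of the
top-100 differentially expressed genes (Wilcoxon rank-sum vs the same
control group).

A negative-binomial simulator with a planted, type-modulated response
program (`simulate_dataset()`) makes the whole pipeline testable offline.

## Worked example

```r
library(perturbOT)

# a desk-scale synthetic world: 3 cell types, unpaired conditions,
# 300 genes of which 50 carry the response program
sim <- simulate_dataset(sim_config(n_cell_types = 3,
                                   cells_per_type_per_condition = 100,
                                   n_genes = 300, n_response_genes = 50,
                                   seed = 1))

cfg <- run_config(seed = 1, latent_dim = 16, hidden_widths = c(64, 64),
                  epochs = 30, batch_size = 64, hvg_count = 250,
                  min_genes_per_cell = 30, min_cells_per_gene = 3)

out <- run_subexperiment(sim$dataset, "type1", cfg)  # ~1 min on one CPU
out$report
#> eval_report over 250 genes:
#>   mean regression:     R^2 = 0.9330 (95% CI 0.9148-0.9474, p = 1.47e-147)
#>   variance regression: R^2 = 0.2172
#>   DEG overlap: 46 / 100
```

The mean regression says the predicted per-gene means of the held-out
type's stimulated state track the observed ones (R² close to 1 is better).
The DEG overlap counts how many of the top-100 differential genes
(predicted vs control) coincide with the observed ones; with only 50
programmed genes, both top-100 lists carry a noise-ranked tail, so ~55 is
the reproducibility ceiling here and 46 means most of the program was
recovered. Larger worlds do better — the full-scale fixture in
`tests/testthat/test-acceptance.R` (1000 genes, 100 programmed, 400 cells
per condition, 100 epochs) reaches R² = 0.96 and overlap 66/100.
`run_all()` repeats the sub-experiment for every eligible held-out type and
appends the aggregate row that out-of-sample benchmarks report.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "perturbot.R", package = "perturbOT"))')
Rscript $CLI simulate --types 3 --cells 400 --genes 1000 --response 100 --seed 0 --out sim.tsv
Rscript $CLI run-all --data sim.tsv --seed 0 --out results/
Rscript $CLI sweep   --data sim.tsv --seed 0 --out sweep/   # 10–100% training fractions
```

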