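# spatialDG

Unsupervised identification of **spatial domains** — spatially coherent
tissue regions sharing a gene-expression program, such as cortical layers or
tumour compartments — in spatially resolved transcriptomics (10x Visium,
Stereo-seq, Slide-seqV2 and similar array-based platforms). The intended
users are computational biologists who have a spot-by-gene UMI count matrix
plus 2-D spot coordinates and want domain labels, denoised expression and
low-dimensional embeddings without any manual annotation.

## Method

Two graphs over the n spots are built:

- a **spatial graph** A_s with `A_s[i,j] = 1` iff the Euclidean distance
  between spots i and j is at most a radius r (550 for Visium-scale pixel
  coordinates, covering a spot's six hexagonal neighbours; 50 for
  Slide-seqV2);
- a **feature graph** A_f linking each spot to its k = 15 nearest
  neighbours under cosine similarity of preprocessed expression,
  symmetrised by union.

A multi-view GCN encoder (two layers, d → 128 → 64) runs three branches —
spatial convolution H_s over A_s, feature convolution H_f over A_f, and a
*co-convolution* sharing one weight set across both graphs whose two outputs
are averaged into H_c and pulled together by a consistency loss on their
spot-similarity (Gram) matrices. A per-spot attention head softmax-weights
the three views and a linear layer fuses them into the embedding H.

Training jointly minimises

```
L = alpha * L_ZINB + beta * L_con + gamma * L_reg + delta * L_DGI
    (alpha = 10.0, beta = 0.1, gamma = 0.1, delta = 0.15)
```

- **L_ZINB** — negative log-likelihood of the raw counts under a
  zero-inflated negative binomial with per-spot-per-gene dropout pi, mean mu
  and dispersion theta decoded from H;
- **L_con** — squared Frobenius distance of the two co-convolution Gram
  matrices;
- **L_reg** — attraction of spatially adjacent embeddings minus a weighted
  repulsion of sampled non-neighbour pairs;
- **L_DGI** — a Deep-Graph-Infomax objective: a bilinear discriminator with
  a spatial-degree bias separates true (spot, global-summary) pairs from
  *hard negatives* — the most cosine-similar spot outside each spot's
  spatial and feature neighbourhoods, re-mined every epoch.

Domains are finally called with K-means (k-means++ init, 10 restarts) on H;
agreement with ground truth is scored by the adjusted Rand index (ARI).

## Worked example

```r
library(spatialDG)

ds  <- easy_benchmark(seed = 0)        # 1000 spots, 5 striped domains, ZINB counts
res <- run_spatialdg(ds, K = 5, radius = 150, knn = 15,
                     cfg = train_config(seed = 1, max_epochs = 100, patience = 99))
print(res)
#> sdg_result: 1000 spots, 5 domains, 100 training epochs, ARI vs ground truth 1.000
head(res$history[, c("epoch", "l_zinb", "l_total")], 3)
#>   epoch   l_zinb  l_total
#> 1     1 1.394025 14.16135
#> 2     2 1.390229 14.11901
#> 3     3 1.386646 14.08399
```

`res$ari = 1.000` means the called domains match the planted stripes
exactly; `l_zinb` is the per-entry ZINB negative log-likelihood of the raw
counts (falling as the decoder learns the count distribution) and `l_total`
the weighted sum of all four objectives. For comparison, expression-only
PCA + K-means on the same data reaches ARI ≈ 0.94: the spatial graph and
contrastive terms close the remaining gap.

From a shell:

```sh
Rscript inst/cli/spatialdg.R simulate --preset easy --seed 0 --out sim.h5ad
Rscript inst/cli/spatialdg.R run --input sim.h5ad --out outdir --clusters 5 \
        --radius 150 --knn 15 --seed 1
Rscript inst/cli/spatialdg.R evaluate --pred outdir/domains.csv --truth truth.csv
```

`run` writes `result.h5ad` (embeddings in `obsm["X_spatialdg"]`, labels in
`obs["spatialdg_domain"]`, denoised expression in
`layers["spatialdg_imputed"]`), `domains.csv`, `history.csv` and a
checkpoint.

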