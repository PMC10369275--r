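# dce3d — de novo 3D spatial reconstruction of transcriptomes

Spatially resolved experiments such as Geo-seq microdissection profile
small pools of cells whose tissue coordinates are known by design;
ordinary bulk-piece or single-cell RNA-seq loses those coordinates.
When samples from the same spatial position have similar transcriptomes,
the sample–sample association structure of the expression matrix is
enough to reconstruct the spatial organisation *de novo*. `dce3d` is an
R implementation of a coalescent network-embedding approach (D-CE) to
that reconstruction, for computational biologists working with
oligo-cell or single-cell expression matrices:

1. **Network construction** — a sample distance network from Spearman
   (`SD = 1 − RCC`), Pearson (`PD = 1 − PCC`) or Euclidean distance, or
   a correlation network soft-thresholded by the connectivity
   specificity index
   `CSI_ij = #{k : c_ik < c_ij − 0.05 and c_jk < c_ij − 0.05} / n`,
   reversed into distances and completed by graph shortest paths.
   Default: square-rooted `PD` below 150 samples, `PCC_CSI` above.
2. **Coalescent embedding** — the doubly centred kernel `X̄ = JXJ` is
   decomposed by SVD; the top-3 scaled singular vectors give angular
   coordinates, and radii follow the heterogeneity-adaptive rule
   `HAr_i = 1 − β/(ln(o_i)+1)` with `β = RSD/(1+RSD)` over the node
   strengths (rank `o_i = 1` for the strongest node).
3. **Marker nomination (EOC)** — every gene is scored by its maximum
   |Spearman correlation| with a rotated embedding axis over a 30 × 30
   grid of orientations (12° steps); orthogonal top markers come from
   k-means clusters of the orientation profiles.
4. **Template fitting (D-CE-t)** — samples are mapped one-to-one onto a
   supplied position template by entropic (Gromov–Wasserstein style)
   optimal transport over kNN-geodesic costs, optionally weighted by
   marker expression; `scmap` mode maps single cells to their
   maximum-probability position instead.
5. **Evaluation** — ordering index (OI, nearest-centroid layer
   chaining), angular separation index (ASI, best central-hyperplane
   split on the unit sphere), projection separability (PSImcc, best
   Matthews correlation along centroid lines), label-randomisation
   normalisation and max-rank strategy selection.

A deterministic synthetic-tissue generator (planar grids and layered
ellipsoid shells with planted gradient, lineage-confound and noise
genes) makes the whole pipeline testable without any external data.

## Worked example

```r
library(dce3d)

tis <- generate_grid_tissue(seed = 1)   # 10 x 10 tissue, 100 genes
emb <- dce_embed(tis$expr)              # network + coalescent embedding
emb
#> Coalescent embedding of 100 samples in 3 dimensions
#>   metric: PD  beta: 0.1562  top singular values: 4.774, 3.747, 2.882

evaluate_embedding(emb, layers = tis$layers, groups = tis$domains)
#> OI = 0.9879  ASI = 0.8825  PSImcc = 0.76

template_oi(emb$cartesian, tis$true_coords[, c("x", "y")])
#>      OI_x      OI_y
#> 0.9878788 0.9272727

scan <- eoc_scan(tis$expr, emb$cartesian)
select_markers(scan, template_dim = 2)
#> Spatial marker genes: gradx_07 (EOC 0.732, cluster n=4); grady_12 (EOC 0.754, cluster n=1)
```

Reading the numbers: the x-column layer order of the planted grid is
recovered almost perfectly (OI 0.99 against layers, 0.99/0.93 per true
axis — 1 is a perfect nearest-centroid chain), the four planted
quadrants separate cleanly on the angular coordinates (ASI 0.88 of a
maximum 1), and the two nominated spatial markers are a planted
x-gradient and a planted y-gradient gene, i.e. the two orthogonal
spatial axes found without any annotation. `fit_template()` would then
pin these samples onto a grid template one-to-one; see the vignette
(`vignettes/spatial-reconstruction.Rmd`) for the model details, the
template-fitting objective, and all tunable parameters.

A thin command-line front end is included:

```sh
Rscript inst/cli/dce.R simulate --out sim --seed 3
Rscript inst/cli/dce.R embed --expr sim/expression.tsv --out run
Rscript inst/cli/dce.R markers --expr sim/expression.tsv \
        --coords run/coordinates.tsv --out run
```

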