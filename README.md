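# mnctess

Maximal nucleus clustering (MNC) and Rényi entropy profiling of
tessellated 2D images, with temporal descriptor matching across frame
sequences.

## What it does, and for whom

Functional imaging slices — and 2D grayscale rasters in general — can be
analysed geometrically instead of through signal statistics: tile the
image into convex polygons, find the structurally singular polygons, and
measure how much information the singular set carries relative to the
rest. `mnctess` implements that programme for researchers in biological
image analysis:

1. **Gradient-orientation seeding.** For image `img(x, y)` the gradient
   orientation at a pixel is `θ = arctan(Gy / Gx)` with
   `Gx = ∂img/∂x`, `Gy = ∂img/∂y` (central differences; two-argument
   arctangent folded into `[−90°, 90°)`). Pixels whose quantized
   orientation is unique in the image become the generating points `S` —
   every seed carries a distinct orientation description.
2. **Bounded Voronoï tessellation.** Each generating point `s` owns the
   region `V(s) = {x ∈ E : ‖x − s‖ ≤ ‖x − q‖ for all q ∈ S}`, clipped to
   the image rectangle. Two regions are *strongly near* when they share a
   boundary edge of positive length (vertex contact does not count).
3. **Maximal nucleus clusters.** A nucleus cluster is a region together
   with all regions strongly near it; a *maximal* nucleus cluster (MNC)
   is one whose nucleus attains the highest adjacent-region count in the
   tiling. Ties are preserved — images frequently carry several MNCs.
4. **Rényi entropy profiling.** With occurrence probabilities
   `p(x) = 1/area(x)` (literal, or normalized over the set), the Rényi
   entropy `H_β(X) = 1/(1−β) · log2 Σ p(x_i)^β` is swept over
   `1.1 ≤ β ≤ 2.5` for the MNC region set and its complement, giving an
   information comparison between the singular zones and the background.
5. **Temporal matching.** Per frame, each MNC is described by the feature
   vector (nucleus gradient orientation, adjacent-region count). Frames
   whose descriptors agree within tolerance are *matching descriptions*;
   frames opposite each other on the uniformly-spaced temporal circle are
   *antipodal pairs*; the principal-MNC centroid gives a trajectory table
   for downstream comparison.

A seeded synthetic generator (Gaussian-blob images, planted repeated
frames, translating blobs) makes the whole pipeline testable without any
external data.

## Worked example

```r
library(mnctess)

img    <- make_blob_image(64, 64, random_blob_config(7), noise_sd = 0.01, seed = 7)
tiling <- tessellate_image(img)     # gradient -> unique-orientation seeds -> Voronoi
glance(tiling)
#> # A tibble: 1 × 5
#>   n_regions n_adjacent_pairs max_degree n_mnc total_area
#> 1       300              764         12     1       4096

find_maximal_nucleus_clusters(tiling)
#> # A tibble: 1 × 4
#>   nucleus_id degree adjacent_ids is_maximal
#> 1        211     12 <int [12]>   TRUE

entropy_profile(tiling, model = "inverse-area")
#> <entropy_profile> model inverse-area; 13 MNC vs 287 non-MNC regions; beta in [1.1, 2.5]
#> # A tibble: 15 × 3
#>    beta  h_mnc h_nonmnc
#> 1   1.1 -18.3     -68.8
#> 2   1.2  -8.53    -34.0
#> ...
```

The tiling of this 64×64 three-blob image has 300 regions; the unique
maximal cluster's nucleus touches 12 neighbours, so the MNC set holds 13
regions against 287 background regions. Under the literal `p = 1/area`
model the MNC entropy exceeds the background entropy at every `β` (the
values are negative because the occurrence probabilities are deliberately
unnormalized). `autoplot(tiling)` draws the tessellation with the MNC
shaded; `autoplot()` on the profile draws the β-sweep curves.

For sequences, `mnc_pipeline()` runs everything and writes deterministic
CSV/JSON artifacts:

```r
seqr   <- make_repeat_sequence(13, list(c(1L, 12L)), seed = 0)
report <- mnc_pipeline(seqr$images, output_dir = "out")
dplyr::distinct(report$matches, i, j)   # the planted pair: frames 1 and 12
antipodal_pairs(12)                     # (0,6) (1,7) ... (5,11), 180° apart
```

A thin command-line wrapper lives at `inst/scripts/mnctess.R`
(`Rscript mnctess.R run --input <dir> --out <dir>`, plus a `fixtures`
subcommand).

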