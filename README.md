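# musclemorph

Quantitative 3D image analysis of muscle architecture, built around the
two fluorescence channels a muscle biologist typically acquires: an
actin/myofibril channel (phalloidin) and a mitochondria channel
(matrix- or outer-membrane-targeted GFP). The package targets the
comparison of *fibrillar* flight-muscle organisation (individualised,
laterally unaligned myofibrils, mitochondria squeezed in between) with
*cross-striated* and *tubular* leg-muscle organisation (laterally
registered sarcomeres; myofibrils on a cylindrical shell with a
mitochondria-rich core).

Four things are computed:

1. **Mitochondria segmentation** — Gaussian prefilter, per-slice Otsu
   thresholding (the threshold is reset on every z-plane to correct for
   depth-dependent signal loss), h-maxima-seeded distance-transform
   watershed for splitting touching organelles, 3D connected-component
   labelling at 6/18/26 voxel connectivity, and size (min-voxel) plus
   border filtering. The distance transform is computed in physical
   micrometres, so strongly anisotropic stacks are handled correctly.
2. **3D morphometry and shape classes** — per object: volume, centroid,
   and the moment-equivalent solid ellipsoid (full axis lengths
   `2 * sqrt(5 * lambda)` from the eigenvalues of the physical-coordinate
   covariance). From the sorted axes `L >= W >= T`, the shape
   descriptors
   `elongation = L / ((W + T) / 2)` and `flatness = W / T`
   classify each object: **sphere** if both < 1.3, **rod** if
   elongation > 2.5, **ellipsoid** otherwise.
3. **Cross-striation index** — the lateral-alignment score of a
   myofibril array. From a start M-band, a path connects the nearest
   M-band (Euclidean, physical units) of each successive myofibril;
   the index is `L_perp / L_path`, the straight perpendicular
   first-to-last-myofibril distance over the path length. Perfect
   registration gives exactly 1; axial misregistration gives < 1.
4. **Mitochondria content** — per-slice Otsu areas of each channel,
   mitochondria-to-actin area ratio, and for tubular fibres the
   peripheral (actin annulus) versus central (enclosed core) partition
   of every cross-section after reslicing the stack along the tube
   axis.

Because public image accessions for this kind of data are rare, the
package ships a **synthetic-volume generator** with voxel-level ground
truth (ellipsoid populations, striation patterns with controllable
M-band jitter, tubular fibres with a prescribed central-mitochondria
fraction, plus a blur/depth-decay/shot-noise imaging model). Every
stage of the pipeline is tested against that ground truth.

## Worked example

```r
library(musclemorph)

# fibrillar workflow on a synthetic cross-striated muscle
cfg <- pipeline_config(seed = 1,
  layout = list(n_myofibrils = 8, layout_kind = "cross_striated"))
res <- run_pipeline(cfg, "fibrillar", out_dir = "run1")
summarize_classes(res$morphometrics)
#>   shape_class  n volume_mean_um3 volume_sd_um3
#> 1      sphere  0              NA            NA
#> 2   ellipsoid 11        3.493455     0.8336940
#> 3         rod  5        2.089600     0.4713945
res$cross_striation_index
#> [1] 1
```

The generator placed 20 mitochondria-like objects; after imaging-model
noise, watershed splitting and the 100-voxel/border filter, 16 objects
survive, mostly elongated ellipsoids of a few cubic micrometres — the
morphology expected in fibrillar muscle. The cross-striation index is
exactly 1 because the synthetic M-bands are laterally registered.

```r
# index of two 10-um-spaced myofibrils whose M-bands are 5 um out of
# register: straight/path = 10 / sqrt(10^2 + 5^2)
cross_striation_index(striation_field(c(0, 10), list(0, 5)))
#> [1] 0.8944272

# physical volume of a 100-slice, 704 x 704 px stack at 10 nm pixels
# and 30 nm slice depth
physical_volume(grid_spec(c(100, 704, 704), c(0.03, 0.01, 0.01)))
#> [1] 148.6848   # ~149 um^3

# tubular workflow: recover a 70 % central mitochondria fraction
cfg_t <- pipeline_config(seed = 1,
  grid = list(shape = c(100L, 40L, 100L), voxel_size = c(0.1, 0.2, 0.1)),
  imaging = list(psf_sigma = c(0.15, 0.15, 0.15), noise_scale = 0.05,
                 background = 0.02))
res_t <- run_pipeline(cfg_t, "tubular", out_dir = "run2")
res_t$report$central_mito_fraction
#> [1] 0.705
```

Each `run_pipeline()` call writes CSV tables (morphometrics, class
summary, striation index or per-slice/summary content), label TIFFs
with YAML voxel-size sidecars, and a JSON provenance log to its output
directory; fixed seeds reproduce the CSVs byte-identically.

A command-line front end over the same functions is installed at
`inst/cli/musclemorph.R` (subcommands `simulate`, `segment`, `measure`,
`striation`, `content`, `run`).

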