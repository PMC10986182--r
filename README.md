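# fibrosim

Ventricular tissue simulation for comparing **representations of myocardial
fibrosis** in arrhythmia modeling. Starting from a normalized
late-gadolinium-enhancement (LGE) intensity map, the package builds two
families of electrophysiological substrates —

* **cleft models**: element connections are severed with probability
  `p = p_max · I · |cos θ|^α` (LGE intensity `I`, angle `θ` between the face
  normal and the fiber-sheet normal), creating interstitial no-flux
  boundaries, graded by a global cleft-density index `fib_max` 0–9, with
  optional step-wise conductivity reduction over LGE intensity bands and
  ionic remodeling of fibrotic myocytes;
* **non-cleft models**: a dense fibrotic *core* (non-conducting `1e-7` S/m or
  slowly conducting `0.01` S/m, core size 25/50/75% below the intensity
  maximum) inside a reduced-velocity *border zone* —

and runs anisotropic **monodomain** reaction–diffusion simulations with a
human ventricular myocyte model (ten Tusscher 2006 kinetics plus the
O'Hara–Rudy late sodium current; hypertrophic-cardiomyopathy remodeling
factors in fibrotic tissue). Programmed **S1–S4 extrastimulus pacing** from
segment-centered electrodes probes inducibility; reentry is detected from
per-element activation records, **back-traced on the adjacency graph in
10 ms steps** to its initiation clusters, characterized by local LGE
features within 5 mm, heuristically labeled Type 1 (channel meander in dense
LGE) or Type 2 (interface rotor in low LGE), and aggregated per segment for
**negative binomial** association tests between fibrosis burden and reentry
counts. A synthetic geometry/LGE generator makes the whole pipeline
reproducible at desk scale with no imaging data; all randomness forks from
one master seed.

The simulation core (membrane kinetics, monodomain stepper) is compiled
(Rcpp); everything user-facing takes and returns tibbles and chains with the
pipe.

## Worked example

```r
library(fibrosim)

# a 64 x 64 sheet (530 um elements) with a 12 mm fibrotic patch
spec <- synthetic_spec(grid_shape = c(64, 64), patch_radii = 12,
                       noise_sd = 0.05, seed = 11)
mesh <- generate_mesh(spec)
lge  <- generate_lge(spec, mesh)

# cleft model at the highest cleft density, with conductivity reduction
# and ionic remodeling of the fibrotic region
model <- build_tissue_model(mesh, lge, "cleft_gm", level = 9, seed = 11)
model
#> <fs_model> cleft_gm (level 9), 4096 elements (0 pruned), 1471 remodeled

# programmed stimulation from the segment-11 electrode
segments <- generate_segments(mesh, 17)
sites    <- select_pacing_sites(mesh, segments)
prot     <- protocol_spec(s1_count = 2, s1_cl = 500,
                          fixed_couplings_ms = c(360, 330, 305),
                          capture_window_ms = 350, observe_ms = 3000)
run <- run_protocol(model, sites[11, ], prot)
run
#> <fs_run> site 11: 4 captured stimuli (2 extra), reentry YES (unsustained)

# trace the reentry to its initiation sites and characterize them
clusters <- trace_initiation(run$reentrant, mesh, min_cluster = 1)
feats    <- local_lge_features(clusters, mesh, lge)
dplyr::bind_cols(feats[c("t_ms", "x_mm", "y_mm", "size", "mean_lge_pct")],
                 classify_morphology(feats))
#> # A tibble: 7 x 7
#>    t_ms  x_mm  y_mm  size mean_lge_pct morphology morphology_source
#>   <dbl> <dbl> <dbl> <int>        <dbl> <chr>      <chr>
#> 1  1190  21.2  15.6     2         63.0 Type1      heuristic
#> 2  1200  23.1  15.6     1         46.4 Type1      heuristic
#> 3  1360  16.7  21.5     1         61.8 Type1      heuristic
#> 4  1450  18.8  16.7     1         79.5 Type1      heuristic
#> 5  1460  19.9  16.4     2         73.9 Type1      heuristic
#> 6  1460  20.4  15.1     1         67.5 Type1      heuristic
#> 7  1480  19.3  17.2     1         77.0 Type1      heuristic
```

Two extrastimuli suffice: the S3 wave blocks into the refractory remodeled
patch, detours, and re-excites it retrogradely through cleft channels —
the substrate mechanism the `fib_max` ladder dials up. The initiation
clusters all sit in dense LGE (mean 46–80% within 5 mm), the channel-meander
("Type 1") pattern. At `level = 0` the same protocol finds essentially no
reentrant activation.

Single-cell behavior:

```r
healthy <- pace_single_cell(cell_params(), bcl = 500, n_beats = 1000)
hcm     <- pace_single_cell(apply_hcm_remodeling(cell_params()),
                            bcl = 500, n_beats = 1000)
c(healthy = healthy$apd90, hcm = hcm$apd90)
#>  healthy      hcm
#> 275.3741 333.5716
```

## Layout

* `R/`, `src/` — generators, substrate construction, solver, protocol,
  reentry tracing, statistics; compiled membrane/monodomain core.
* `vignettes/fibrosis-representations.Rmd` — the model, its assumptions,
  parameter defaults and numerical choices.
* `inst/cli/fibrosim.R` — thin command-line wrapper
  (`generate`, `build-model`, `simulate`, `analyze`, `stats`, `run-study`).
* `tests/testthat/` — unit, property and acceptance suites.
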