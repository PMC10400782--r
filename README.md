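# voidshape

Solvent cavity shape descriptors and solvation regression for explicit-water
snapshots.

## What it does, and for whom

The solvent void hosting a small solute in water is larger and far more
irregular than the solute's own van der Waals surface: it grows finger-like
*branches* of empty space between the surrounding waters.  `voidshape` is
for molecular-simulation practitioners who want to quantify that shape and
relate it to solvation thermodynamics and hydrophobicity.

The analysis chain:

1. **Void extraction** — remove the solute, treat water O/H as spheres
   (radii 1.52 / 1.2 Å), tessellate the centers, and keep a *probe sphere*
   at every Voronoi vertex whose empty radius is ≥ 1.2 Å.  Probes connected
   through passages with *bottleneck* ≥ 1.1 Å merge into voids; the void
   with maximal overlap with the solute region is the host.
2. **Surface** — a watertight alpha-shape mesh of the host void with an
   edge-weighted surface graph.
3. **Descriptors** — volume *V*, area *S*, longest surface geodesic *L*
   (weighted graph diameter), branch count `nbr` from density-peak
   clustering of surface vertices more than 5 Å from the solute, branch
   lengths `dmin`/`dmax`/`dave`/`dtotal`, and branch density
   `nbr / N^(2/3)` (*N* = heavy atoms).
4. **Regression** — standardized intercept-free linear models
   *y* = Σ<sub>j</sub> *w*<sub>j</sub> *X*<sub>j</sub> with exhaustive
   subset search scored by leave-one-out cross-validation
   (R², R²<sub>LOO</sub>, MSE<sub>LOO</sub>), plus leave-*k*-out
   error-scaling diagnostics
   (Error<sub>i</sub>·√(N−i)) / (Error<sub>1</sub>·√(N−1)).

A synthetic-data module generates water-like sphere packings and *phantom
cavities* (spheres, *k*-tendril stars) with analytic ground truth, so the
whole chain is testable without MD output.  See the vignette
(`vignettes/cavity-shape-analysis.Rmd`) for the models, parameter meanings
and design choices.

## Worked example

Carve a 4-tendril star cavity (tendrils 8 Å long) into an ambient-density
synthetic bath, seal it with a model solute, and measure it:

```r
library(voidshape)
bath <- generate_water_bath(30, 33.4, seed = 1)          # ~902 waters
cv   <- carve_phantom_cavity(bath, "star", core_radius = 3, n_tendrils = 4,
                             tendril_length = 8, seed = 2)
cfg  <- place_model_solute(cv$config,
          data.frame(dx = 0, dy = 0, dz = 0, element = "C", radius = 3,
                     group = "core"))
ext  <- extract_host_void(cfg)
print(ext$graph)
#> Probe graph: 385 probe spheres, 592 edges (probe 1.20 A, bottleneck 1.10 A)

surf <- build_surface(ext$host, ext$graph)
br   <- detect_branches(surf, cfg)             # threshold 5 A
desc <- summarize_descriptors(surf, br, n_heavy_atoms(cfg))
round(as.data.frame(desc), 2)
#>        V      S     L nbr dmin dmax dave dtotal branch_density n_heavy
#> 1 877.96 620.65 25.26   4 7.78 8.04 7.93  31.72              4       1
```

The detector finds exactly the 4 carved tendrils, each with length within
0.25 Å of the 8 Å ground truth (`dmin`–`dmax` 7.78–8.04).  *V* and *S*
exceed the carved-region values because the surrounding waters cannot
conform to a 1.8 Å-thin tendril; on spherical phantoms, where the shell
packs to contact, both recover the analytic values to a few percent
(see `scripts/acceptance.R` output below).

Regression on a 20-row feature table:

```r
fx  <- generate_regression_fixture(20,
         c(V = 0.8, S = -0.6, L = 0, nbr = 0, dmin = 0, dmax = 0,
           dave = 0, dtotal = 0), noise_sd = 0.1, seed = 4)
fit <- best_subset(cbind(fx$X, y = fx$y), "y", names(fx$X))
fit$features   # contains "V" and "S"
fit$r2_loo
```

A thin command-line front end ships in `inst/cli/voidshape`
(`simulate`, `phantom`, `describe`, `aggregate`, `fit` subcommands).

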