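# swarmphage

Quantitative analysis of **active phage transport by bacterial swarms**:
from single-particle tracks of fluorescent phages, through physical
transport prediction, to fluorescence-image read-outs of what delivered
phages do to their prey.

Motile, vortexing swarms (e.g. gliding *Capnocytophaga* on wet agar)
secrete a flowing fluid layer that can carry non-host phages far faster
than diffusion would. A lambda-phage capsid of radius $r \approx 30$ nm
has Stokes–Einstein diffusivity $D = k_B T / (6\pi\eta r)$, ~30-fold below
a 1-nm antibiotic; riding swarm flow instead turns its motion advective.
This package is for microbiologists and biophysicists who track such
particles and need the standard analysis chain in one tested toolbox:

* **Motion statistics** — ensemble mean-squared displacement
  $\langle\Delta r^2(\tau)\rangle$, power-law exponent $\alpha$
  ($\alpha = 1$ diffusive, $>1$ actively driven), Einstein-relation
  diffusivity $D = \text{slope}/(2n)$, per-track speeds.
* **Transport modelling** — 1-D Fickian and advection–diffusion
  finite-difference solver
  ($\partial_t C = D\,\partial_x^2 C - v_d\,\partial_x C$, zero-flux,
  upwind advection), swarm vortex-to-linear speed conversion
  $s_2 = s_1/\pi$, Stokes–Einstein calculations, and front-distance
  prediction.
* **Image quantification** — prey-colony biomass clearance from timelapse
  TIFFs (Otsu segmentation, quadratic trend with 95% band, endpoint
  clearance rates and experimental/control rate ratios) and phage
  penetration depth from confocal z-stacks (per-slice coverage, peak
  depth).
* **Synthetic data** — seeded generators for Brownian / fractional-Brownian
  / advective trajectories, shrinking-colony timelapses and biofilm
  z-stacks with ground truth emitted alongside, so every estimator is
  validated end to end.
* **I/O** — tracker "exported tracks" XML, trajectory CSV, multi-page
  TIFF; a YAML run configuration; a CLI (`exec/swarmphage`) with
  `track-stats`, `predict`, `simulate`, `biomass`, `depth` and `synth`
  subcommands.

## Worked example

Generate swarm-carried (advective) phage tracks, classify their motion,
and predict how far a swarm delivers phages:

```r
library(swarmphage)

# 60 tracks, drift 20.71 um/min over weak diffusion, 1 frame/s
gen <- gen_trajectories("advective", D = 0.01, v = 20.71,
                        n_steps = 120, n_particles = 60, seed = 7)
res <- motion_summary(gen$ensemble)
res$fit
#> <power_law_fit> alpha = 1.943, r^2 = 0.9999 over lags 1-30 s
res$class
#> <motion_class> superdiffusive (alpha = 1.943, band 0.9-1.1)
res$speed
#> <speed_stats> 60 tracks, mean 22.59 +/- 0.63 um/min

# transport prediction: swarm-fluid D, linear speed from a 20 um/min vortex
pred <- predict_travel_distance(D = 0.228, v_d = swarm_linear_speed(20),
                                t = 3.3)
pred$distance_um
#> [1] 1507
```

The exponent near 2 says the drift-dominated tracks are ballistic, not
diffusive — transport is active. The mean speed recovers the generator's
drift (path-length speeds run slightly high because diffusion adds
wiggle). The front prediction says a swarm advancing at
$20/\pi = 6.37$ µm/min carries a detectable (1%-of-peak) phage front
~1,500 µm in 3.3 h — the design basis for placing a prey colony 1 mm away.

Depth penetration from a synthetic biofilm z-stack (36 slices, 3-µm step)
with phages delivered mid-biofilm:

```r
bz <- gen_biofilm_zstack(seed = 42)   # spot density peaked at 50 um
phage_depth_profile(bz$stack)
#> <depth_profile> 36 slices, 0-105 um; peak coverage 0.471 at 51 um
```

The same call on a surface-exponential control puts the peak at 0 µm —
phages stuck on top of the biofilm.

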