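# earmap: binaural auditory scene analysis by active head rotation

A two-microphone array cannot, from a single observation, tell front
from back, and above ~1.2 kHz (for a 14.5 cm baseline) the interaural
time difference (ITD) cue produces multiple phantom images through
spatial aliasing. `earmap` implements an *active hearing* analyzer that
resolves both ambiguities with nothing but ITD: the head rotates through
a schedule of poses, and egocentric spectral-spatial evidence is fused
across poses into a 360° world-centred probability map. Because a real
source reinforces the same world azimuth at every head orientation while
its phantom and mirror images wander, the recursive product collapses
onto the true locations - and, because evidence competes within
frequency bands, the map simultaneously unmixes the sources' spectra.
The package is aimed at researchers in computational auditory scene
analysis, robot audition, and auditory neuroscience who want a fully
simulated, reproducible testbed for rotation-based ITD disambiguation.

## The model

Per 4096-sample stereo frame at sampling rate $f_s$:

1. **Gammatone filter bank** - 50 linearly spaced bands, 100-5000 Hz,
   4th-order, bandwidth $1.019\,\mathrm{ERB}(f_c)$.
2. **EPSP transform** - each band signal becomes a train of Gaussian
   pulses (1 ms total duration) at its positive-going zero crossings,
   keeping phase-locked timing and discarding amplitude.
3. **Delay-and-sum beamformers** - beams at every whole-sample lag
   $k = -K..K$, $K = \lfloor d f_s / c \rfloor$ (41 beams for
   $d = 0.145$ m, $f_s = 48$ kHz, $c = 343$ m/s), steered at
   $\theta_b = \arcsin(cT_b/d)$; frame RMS gives the egocentric
   bands × beams energy image $S_{f,b}$, validated against the analytic
   response $A(\psi,\theta) = \sqrt{2+2\cos(2\pi f d(\sin\psi-\sin\theta)/c)}/2$.
4. **Evidence** - per band: spline-resample beam energies onto 1°,
   mirror across the interaural axis, normalise to sum to one
   (Jeffress-style place code turned into a per-band probability).
5. **Recursive Bayesian fusion** - rotate the evidence into world
   coordinates and multiply it into the allocentric map
   $\mathrm{PDF}^{allo} \propto \prod_r \mathrm{PDF}_r^{allo}$, with
   per-band renormalisation; initialised uniform.

Performance is quantified by localization error (summed circular
distance from true azimuths to the nearest of the two most prominent
peaks of the frequency-collapsed map), spectral correlation (Pearson
correlation between true and map-estimated source-spectrum differences),
and peak width. See the methods vignette
(`vignettes/active-binaural-mapping.Rmd`) for conventions, parameters
and design rationale.

## Worked example

Broadband noise at 0° and a 2400 Hz tone at 11° - instantaneously the
tone is aliased and both sources are front/back ambiguous:

```r
library(earmap)
cfg <- read_experiment_config(system.file("configs", "fig4.yaml",
                                          package = "earmap"))
res <- run_experiment(cfg, verbose = TRUE)
res$metrics[, 1:4]
#>    rotation head_deg localization_error_deg spectral_correlation
#> 1         0        0                     11                   NA
#> 2         1       20                     11               -0.168
#> 3         2       40                     11               -0.215
#> 4         3       60                     11               -0.204
#> 5         4       80                      1                0.639
#> 6         5      100                      1                0.653
#> 7         6      120                      1                0.661
#> 8         7      140                      1                0.666
#> 9         8      160                      1                0.668
#> 10        9      180                      1                0.673
res$peaks
#>   angle_deg height prominence lo_deg hi_deg width_deg
#> 1         0 0.0448    0.04483    355      5        11
#> 2        10 0.0337    0.00709      9     11         3
```

Early in the scan the two sources share one ambiguous image (error 11°:
the tone has no peak of its own). As the head sweeps past the sources
the phantom images are multiplied away: the final map has two distinct
peaks at 0° and 10° (1° from the tone's true azimuth) and the
correlation between the estimated and true spectral difference climbs to
0.67 - the scene is resolved in space *and* frequency.
`plot(res$final_map)` shows the spectral-spatial map itself.

A command-line interface wraps the same machinery:

```sh
Rscript inst/exec/earmap run --config inst/configs/fig4.yaml --out results/fig4
Rscript inst/exec/earmap sweep --config inst/configs/fig5_sweep.yaml \
    --frequencies 300,600,1200,2400,4800 --separations 11,22
Rscript inst/exec/earmap simulate --config inst/configs/fig7.yaml --wav scene.wav
```

(after installation the script lives at
`system.file("exec", "earmap", package = "earmap")`).

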