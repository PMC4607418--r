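# fruitmc

Monte Carlo simulation of near-infrared light transport in stone fruit
(drupes), for designing reflectance-mode fruit quality inspection.

A peach under a spectrometer probe is a layered system: a thin, highly
scattering skin over the flesh of interest, with a stone below. `fruitmc`
traces weighted photons through that stack — exponential free paths,
Henyey–Greenstein scattering, Fresnel/Snell boundary crossing, Russian
roulette — and scores where the light goes: total diffuse reflectance
R_d, per-layer absorbed fractions, the fraction lost into the stone, and
spatially, angularly and depth-resolved profiles. On top of the kernel it
provides

* **detection-efficiency statistics** for probe design: P_eff(r), the
  percentage of detected light at source–detector distance r that actually
  interacted with the flesh, and S_flesh(r), the fraction of detected
  pathlength spent in the flesh;
* **diffusion analytics**: the effective attenuation coefficient
  mu_eff = sqrt(3 mu_a (mu_a + (1−g) mu_s)), penetration depths, and
  layered attenuation to the distal flesh boundary;
* **Gaussian beam convolution** of the impulse response (exponentially
  scaled Bessel kernel), turning pencil-beam results into responses to a
  real finite source;
* **scenario runners** for the standard sweeps (core vs no core, skin
  thickness, flesh thickness, ±20% flesh optical properties, exit-angle
  profiles) and a small command-line interface.

## Worked example

```r
library(fruitmc)

st <- preset_stack("table2", flesh_thickness = 2.0)  # measured peach, 808 nm
st
#> <fruit_stack> 2 layer(s), n_above = 1.000, n_below = 1.460
#>   [1] skin n = 1.337, mu_a = 0.075, mu_s = 102.0 cm-1, g = 0.65, d = 0.03 cm
#>   [2] flesh n = 1.342, mu_a = 0.024, mu_s = 28.4 cm-1, g = 0.61, d = 2 cm

res <- run_simulation(st, sim_config(n_photons = 1e5, seed = 42))
tidy(res)
#>   quantity             value    stderr
#> 1 specular_reflectance 0.0208   0
#> 2 diffuse_reflectance  0.785    0.000972
#> 3 absorbed_skin        0.0140   0.0000379
#> 4 absorbed_flesh       0.125    0.000600
#> 5 core_absorbed        0.0554   0.000542
#> 6 roulette_lost        0        NA
```

Reading the budget: 2.1% of the beam reflects specularly at the surface,
78.5% returns as diffuse reflectance, 1.4% is absorbed in the skin, 12.5%
in the flesh, and 5.5% crosses into the stone and is lost. The channels
sum to 1 — the kernel's per-photon bookkeeping is exact.

```r
prof <- radial_profile(res)          # Rd(r), P_eff(r), S_flesh(r)
conv <- convolve_beam(prof, gaussian_beam(energy = 0.5, radius_1e2 = 0.05))
autoplot(res, "detection")           # why the fiber should sit off-axis
diffusion_summary(st)                # mu_eff 0.894 /cm -> 1% depth 5.15 cm
```

Scenario sweeps return tidy tables, e.g.
`scenario_optics_grid(n_photons = 1e6, seed = 1)` runs the five flesh
(mu_a, mu_s) pairs spanning a ±20% range around the measured means and
tabulates each run's energy budget with Monte Carlo standard errors.

A thin CLI wraps the same functions:

```sh
Rscript inst/exec/fruitmc run --config inst/extdata/table2.json \
    --photons 100000 --seed 1 --out results/
Rscript inst/exec/fruitmc analytics --config inst/extdata/table2.json
Rscript inst/exec/fruitmc scenario optics --photons 1000000 --out results/
```

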