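# troutsim

An individual-based aquaculture simulator for rainbow trout
(*Oncorhynchus mykiss*) that couples a Boids-style schooling and feeding
behavior model with a dynamic energy budget (DEB) growth model. It is
aimed at aquaculture researchers and farm planners who want to explore
feeding strategies — how much growth a feeding level buys, how feed
conversion changes with growth stage, and how individual growth
trajectories diverge — without running a live rearing experiment.

## The model in brief

Each simulated day is a 120 s behavioral episode followed by a one-day
growth update.

**Behavior.** Every fish obeys Newton's law `W a = F` (mass in grams,
positions in metres, 0.05 s steps), where `F` is the sum of seven rule
forces — separation, cohesion, alignment, boundary avoidance, inertia,
feed attraction and random motion — each a unit direction scaled by a
dimensionless weight. Fish perceive neighbors and pellets within a sphere
of radius 2 fork lengths, minus a 30° backward dead-space cone. Speed is
capped at `C_maxvel · TL` (1.5 TL/s normally, 7.0 TL/s while feeding).
Pellets are dropped at the surface at 60 s and sink; a pellet within
0.5 FL of a fish is ingested — each pellet by at most one fish — until the
fish reaches its daily cap `S_max = 0.04 W`.

**Growth.** Each fish carries gut content `G` (J), reserve `E` (J) and
structure `V` (cm³):

    dG/dt = k(T) (p_x − p_a)
    dE/dt = k(T) (κ_x p_a − p_c)
    dV/dt = k(T) (κ p_c − p_s) / [E_G]

with food flux `p_x = S·E_f` from the day's intake `S`, assimilation
`p_a = k_g G`, mobilization `p_c`, maintenance `p_s = [p_M] V`, and an
Arrhenius temperature factor `k(T) = exp(T_A/T_1 − T_A/T)`. The system is
integrated with classic RK4 (240 substeps/day). Wet mass is
`W = d_Vw V + E w_Ed d_Vw / (μ_E d_Vd)` and fork length follows from the
allometry `W = a FL^b`. Updated sizes feed back into the next day's
behavior, so feeding success compounds.

See the vignette (`vignettes/trout-aquaculture-simulation.Rmd`) for
parameter tables, the numerical analysis behind the integrator settings,
and the design decisions taken where the underlying description was
silent.

## Worked example

A 30-day feeding-level sensitivity study: 50 fish at 10 °C fed a constant
0.04 g/fish/day of 2 mg crumble, at 0.7×, 1.0× and 1.3× the baseline
level, sharing one seed (hence one initial population):

```r
library(troutsim)

sched <- make_schedule("constant_g", n_days = 30, grams = 0.04)
cfg   <- simulation_config(sched, n_individuals = 50, seed = 1)
sens  <- run_sensitivity(cfg)
print(sens)
#> Feeding-level sensitivity analysis
#>   x0.7   final mean W    2.27 g, mean FL  5.21 cm
#>   x1.0   final mean W    2.56 g, mean FL  5.45 cm
#>   x1.3   final mean W    2.81 g, mean FL  5.62 cm
```

Final mean masses order strictly with feeding level — the qualitative
feeding-response the simulator is built to expose. (At 10 °C this lean
ration is below the stock's maintenance requirement, so all three
scenarios lose mass from the initial ≈3.0 g; more feed means less loss.)
A single run gives per-day detail:

```r
sim <- sens$runs[["1.0"]]
head(summary(sim))
#>  day  n mean_W_g sd_W_g mean_FL_cm sd_FL_cm
#>    0 50    3.014 0.8032      5.749   0.5737
#>    1 50    2.984 0.7883      5.731   0.5649
#>    2 50    2.961 0.7732      5.717   0.5548
#>    3 50    2.938 0.7605      5.703   0.5463
#>    4 50    2.917 0.7485      5.689   0.5407
#>    5 50    2.896 0.7281      5.676   0.5291
```

`sim$records` holds every fish on every day (`W_g`, `FL_cm`, `G_J`,
`E_J`, `V_cm3`, intake `S_g`, pellet count `Nf`); `plot(sim)` draws the
mean ± sd mass trajectory; `compute_fcr()` yields per-interval feed
conversion ratios and `error_metrics()` absolute / percentage errors
against a reference series. A command-line front end
(`inst/cli/troutsim`) wraps simulation, sensitivity analysis, record
analysis and fixture generation; identical configurations and seeds
produce byte-identical `daily_records.csv` files.

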