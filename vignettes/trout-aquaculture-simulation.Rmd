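---
title: "Coupled schooling-behavior and energy-budget simulation of rainbow trout rearing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled schooling-behavior and energy-budget simulation of rainbow trout rearing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`troutsim` simulates a stock of rainbow trout (*Oncorhynchus mykiss*) in a
circular rearing tank over a feeding season. Each simulated day couples two
components:

1. **A behavioral episode** (default 120 s at a 0.05 s time step): every
   fish is an agent whose swimming force is the sum of seven Boids-style
   rule forces. Feed pellets are dropped at the water surface mid-episode
   (default 60 s) and each pellet-fish contact is a feeding event.
2. **A growth day**: the mass each fish ingested during the episode is fed
   to a per-individual dynamic energy budget (DEB) model and integrated
   over one day with 4th-order Runge-Kutta.

The updated mass and fork length feed back into the next day's behavior
(field of view, swimming speed and the intake cap all scale with size), so
behaviorally successful fish grow faster, swim faster, and compete better
for the next day's feed — the central feedback the simulator exists to
capture. At the end of every day all positions are re-randomized so that
spatial patterns do not carry over.

## Behavioral rules

Each rule contributes a *unit direction* scaled by a dimensionless weight,
so no rule's magnitude depends on distances:

| rule | direction | default weight |
|---|---|---|
| separation | away from the nearest visible neighbor | 1.0 |
| cohesion | toward the centroid of visible neighbors | 0.2 |
| alignment | toward the mean neighbor velocity | 0.2 |
| boundary | away from the nearest wall/floor/surface point (only when inside the field of view) | 1.5 |
| inertia | along the current heading | 0.2 |
| feed | toward the nearest visible pellet | 0.0 standard / 3.0 feeding |
| random | uniform random unit vector | 0.2 |

A fish sees neighbors (and pellets) within a sphere of radius twice its
fork length, minus a backward "dead space" cone of half-angle 30 degrees
about the direction opposite to its velocity; a stationary fish has no
dead space. Newton's law is applied with body mass in grams and positions
in metres (`a = F / W`), the convention under which the weights above were
calibrated; forces are therefore not in SI newtons.

Two behavioral modes exist. While feed is present in the tank and a fish's
intake for the day is below `S_max = 4%` of its body mass, it is in
*feeding* mode (feed attraction active, speed cap 7.0 total lengths/s);
otherwise *standard* mode (no feed attraction, 1.5 total lengths/s). After
every kinematic update the speed is hard-capped at the mode's limit and
positions that left the tank are projected 1 mm back inside with the
outward velocity component zeroed.

## Pellets and encounters

The feed source material specifies only that pellets appear at the top of
the tank, so the pellet kinematics are this package's own design,
documented here and configurable in `behavior_params()`:

- `floor(daily mass / pellet weight)` pellets are released at the surface,
  uniformly over a central circle of radius one third of the tank radius;
- pellets sink at 0.01 m/s (they span the 0.6 m column over the 60 s
  remaining in the episode) and expire on reaching the floor;
- a pellet within `0.5 * FL` of an eligible fish is ingested. Each pellet
  is credited to at most one fish — the nearest eligible one, ties broken
  by lower id — and is removed immediately, so double consumption is
  structurally impossible.

Eligibility requires that a whole pellet still fits under the daily cap
(`intake + W_f <= S_max`). The alternative reading — eat whenever
`intake < S_max` — would overshoot the 4% cap by up to one pellet; we
enforce the cap as a hard invariant, checked inline at every step of every
behavioral day.

## Growth model

Each fish carries gut content $G$ (J), reserve $E$ (J) and structural
volume $V$ (cm^3^):

$$\frac{dG}{dt} = \dot k(T)\,(\dot p_x - \dot p_a), \qquad
  \frac{dE}{dt} = \dot k(T)\,(\kappa_x \dot p_a - \dot p_c), \qquad
  \frac{dV}{dt} = \dot k(T)\,\frac{\kappa \dot p_c - \dot p_s}{[E_G]}$$

with food flux $\dot p_x = S\,E_f$ (ingested grams times feed energy
density, held constant across the day), assimilation
$\dot p_a = k_g G$, mobilization
$\dot p_c = \frac{(E/V)\,([E_G]\dot v V^{2/3} + [\dot p_M] V)}{[E_G] + \kappa E/V}$,
and maintenance $\dot p_s = [\dot p_M] V$. All rates are scaled by the
Arrhenius factor $\dot k(T) = \exp(T_A/T_1 - T_A/T)$, equal to 1 at the
reference temperature 293.15 K and about 0.38 at the 10 °C rearing
temperature. Reproduction and maturation buffers are deliberately absent.

Wet mass is bookkept as

$$W = d_{Vw} V + E\,\frac{w_{Ed}\, d_{Vw}}{\mu_E\, d_{Vd}},$$

structural wet mass plus the wet-mass equivalent of reserve energy. The
source presentation of this identity omits the factor $V$ in the first
term, which is dimensionally inconsistent (g/cm^3^ added to g); the form
above is the standard DEB wet-mass bookkeeping and is what we implement.
Fork length follows from mass through the allometry
$W = a\,FL^{\,b}$ ($a = 0.01958$, $b = 2.865$, estimated from paired
measurements of the reference stock), inverted exactly.

## Numerical choices

**Behavioral time step.** The source material prints both 0.025 s (in the
equations) and 0.05 s (in the workflow); we default to 0.05 s, the value
attached to the description of the runs actually performed, and expose it
as `dt`.

**RK4 resolution.** The gut drains at $k_g = 20$/d, so the growth system
is stiff on the one-day scale: the decay rate constant at 10 °C is
$\lambda = \dot k(T) k_g \approx 7.6$/d, and classic RK4 has per-step
relative error of order $(\lambda h)^5/120$. A handful of substeps per day
leaves percent-level error; the package default of 240 substeps/day (a
~6-minute step) puts the gut-decay error below $10^{-6}$, verified against
the closed-form exponential in the test suite. Stage evaluations clamp the
state to its valid region ($G, E \ge 0$, $V \ge 10^{-9}$ cm^3^), and the
state is re-clipped after every substep; non-finite intermediates abort
with a diagnostic rather than propagate.

**Degenerate directions.** Coincident positions (separation, feed) fall
back to a fresh random unit direction; zero velocity means no inertia
force and no dead space; a centroid coinciding with the fish's position
contributes nothing. These choices avoid NaN propagation while preserving
each rule's magnitude contract.

**Initial energy partition.** Only initial mass (via fork length) is
observable. We split it as 30% reserve-equivalent, 70% structure
(`reserve_fraction`, configurable), with an empty gut; the partition
reproduces the target mass exactly by construction. This is an assumption,
not an estimate, and simulated trajectories over the first days depend on
it.

**Ties and determinism.** Simultaneous pellet claims go to the nearest
fish, then the lower id. All randomness flows through R's RNG from the
configured seed, including inside the compiled stepper, so a configuration
plus a seed reproduces a run bit for bit (the record writer is
deterministic too, so output files are byte-identical).

# What the synthetic generator does and does not emulate

`make_population()` reproduces the reference initial stock (n = 212 fish,
fork length 5.68 ± 0.69 cm, truncated at 1 cm). `make_schedule()` builds
constant, percent-of-body-weight, or explicit schedules, assigning the
five commercial feed types by their tabulated day ranges (2 mg crumble
through 110 mg grower pellets). The experimentally recorded daily feeding
series that drove the original season-long comparison is not published and
is **not** emulated; consequently the headline season-scale numbers of
that study (final mean mass near 104 g, season FCRs near 1.1-1.3) are not
reproducible here, and nothing in this package claims them. What the
tests do establish is structural: exact pellet accounting, hard caps,
analytic integration limits, determinism, and the qualitative
feeding-level response.

Also absent, deliberately: mortality and smoltification (population is
constant), density and dissolved-oxygen effects, within-day multiple
meals, hydrodynamics, and pellet dissolution.

## Harvest saturation and the sensitivity study design

Because ingestion requires a physical encounter, a school has a finite
harvest capacity per 60-s feeding bout: once the fast (large) fish have
reached their 4% cap, the remaining fish cannot sweep pellets faster, and
offering yet more pellets only increases waste. (This is the same
mechanism by which large individuals monopolize feed and inflate
between-individual variance.) A feeding-level sensitivity study is
informative only when the offered rations lie *inside* the harvestable
range, so that the manipulated variable — the offered level — actually
modulates realized intake. The packaged study therefore feeds a constant
0.04 g/fish/day of the 2 mg crumble to 50 fish for 30 days at levels
0.7x/1.0x/1.3x with a shared seed; realized intake then tracks the
offered level (the acceptance script reports both), and final mean masses
order strictly with feeding level. At 10 °C this lean ration sits below
the stock's maintenance requirement, so all three scenarios lose mass
slowly; the feeding-level response — less loss at higher levels, strictly
ordered final masses — is the property under study. The capture radius
(`capture_radius_multiplier`, default 0.5 fork lengths) is the natural
calibration knob if a user needs a higher harvest capacity.

# Problem sizes

The test suite runs tiny scenes (3-50 fish, 1-6 days) for unit and
property tests, one full-scale behavioral day (212 fish, 2400 steps) for
the pellet-accounting and cap checks, 100 random 50-fish configurations
against a brute-force field-of-view oracle, and the 50-fish 30-day
three-level sensitivity study. The acceptance script re-runs the
sensitivity study and the full-scale day from scratch, plus a 30-day
growing-stock scenario (50 eleven-centimetre fish on 72 mg pellets at 4%
of initial body mass) on which the feed conversion ratio is well defined.

# Limitations

- Pellet kinematics (release area, sink speed, capture radius) are this
  package's constructions; absolute intake levels depend on them even
  though the accounting invariants do not.
- The reserve/structure split of the initial mass is assumed, not
  estimated.
- Total length is taken equal to fork length by default
  (`tl_over_fl = 1`); no conversion was available, and the speed caps
  scale with it.
- DEB parameters are taken as given (reference-database values for
  *O. mykiss*); no parameter fitting is provided.
- One feeding bout per day; feeding-time semantics beyond "mid-episode"
  are not modeled.
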