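---
title: "Models and methods: the plumebot olfactorimotor platform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: the plumebot olfactorimotor platform}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumebot)
```

plumebot closes a sensorimotor loop around an odor plume: a fluid world
produces concentrations at a moving sensor, a layered neural circuit turns
them into motor-unit firing, a motor-pool mapping turns firing into tread
currents, the robot moves and stirs the fluid, and a genetic algorithm
tunes the circuit's parameters against time-to-source fitness. This
vignette explains each model, its assumptions, the tunable parameters and
their defaults, the numerical choices, and what the synthetic test worlds
do and do not establish about real plumes.

## The plume world

### Governing scheme

The flow solver implements the stable-fluids scheme for incompressible
2-D flow: per 30 ms step, body forces are added to the velocity field,
momentum diffuses implicitly (Gauss–Seidel), the field is projected to be
divergence-free, self-advects semi-Lagrangianly, and is projected again;
each odorant "dye" channel receives its sources, diffuses implicitly,
advects along the velocity field, and decays by the evaporation factor
`exp(-rate * dt)` with a clamp at zero. Implicit diffusion and backward
particle-trace advection make every sub-step unconditionally stable, so
the 30 ms step (and far larger ones) cannot blow up — the property that
makes interactive closed-loop simulation affordable. Real turbulent
plumes are 3-D, intermittent and Reynolds-dependent; this solver trades
those features for speed and reproducibility, which is the intended use.

### Discretization and boundaries

Fields live on a square grid (140 × 140 cells at full scale, one-cell
solid wall ring, default 0.02 m cells). Velocity uses a staggered
(marker-and-cell) layout — `u[i, j]` on the east face, `v[i, j]` on the
north face of cell `(i, j)` — because on a staggered grid the discrete
divergence telescopes to exactly zero over the domain when wall faces
carry no flux, so the pressure solve is compatible and its residual falls
to machine precision with enough sweeps. The projection uses
SOR-accelerated Gauss–Seidel (`sor_omega`, default 1.7); with
`solver_iters = 200` the post-projection divergence is at the 1e-15 level
on a 16 × 16 grid, while the interactive default of 20 sweeps removes
well over 90% of pre-projection divergence. Dye is cell-centered with
zero-flux (mask-aware) stencils at walls, which makes the implicit
diffusion solve conserve total dye exactly; wind and robot forces are
per-step velocity increments.

Two caveats are deliberate. Semi-Lagrangian advection conserves mass only
approximately under nonzero flow (the classic trade-off of the scheme),
so the package's mass-budget guarantees are stated for still air, where
advection is the identity. And when viscosity is zero the pre-advection
projection is skipped — the field entering advection is then the previous
step's projected field plus force increments — halving solver cost at
interactive fidelity; fixtures with nonzero viscosity run both
projections.

### The robot in the fluid

The robot is a 0.12 m × 0.10 m rectangle driven by two treads: currents
`I_L, I_R` (signed 8-bit) set targets `v* = k_m (I_L + I_R) / 2` and
`w* = k_m (I_R - I_L) / W`, attained instantly by default (`tau_motor =
0`, a kinematic model — mass and inertia are not simulated) and decayed
by the friction factor `1 - mu * dt`. Defaults `k_m = 0.004` m/s per
current unit and `W = 0.10` m give ~0.06 m/s at full command, plausible
for a 10 cm robot. Collisions clamp the pose inside the walls, zero the
inward velocity and set proximity to zero (no bounce). The robot feeds
back into the fluid through its leading edge: the edge segment is
supersampled at one sample per cell width, de-duplicated, and each
touched cell receives `-effect_magnitude` times its stored flow vector —
an equal-and-opposite perturbation whose magnitude is a scenario
parameter (default 1). Whether the body should also displace dye directly
is left out: only forces are injected.

## Sensor chemistry

Odorants are vectors of motif degrees over 10 abstract motifs; the motif
concentration a scene presents is `m_a = sum_j C_j d_{j,a}` plus any
background. Sensor `i` binds a random subset of motifs (3 per sensor by
default, `K` drawn log-uniformly from 0.05–5 in normalized concentration
units). Two activation forms are provided:

* the printed single-odorant forms — `A = C d / (C d + K)` for one shared
  motif and `A = C / (C + sum K/d)` for several — evaluated verbatim by
  `steady_state_activation()`. The multi-motif form as printed makes a
  sensor *less* sensitive the more shared motifs the odorant carries
  (the `K/d` terms add), which sits oddly with motifs "acting jointly";
  the package keeps it verbatim for single-odorant work rather than
  silently correcting it;
* the mixture rule used in closed loop: occupancies combine linearly,
  `S = sum_a m_a / K_a`, `A = S / (1 + S)` — the unique first-order form
  that reduces exactly to the single-motif equation and extends to
  multi-odorant scenes.

Finite-rate kinetics `dA/dt = r_f (A_target - A) - r_beta A` (explicit
Euler, sub-stepped if `dt (r_f + r_beta) > 1`) converge to
`A* = r_f A_target / (r_f + r_beta)`; because sensors are assumed fast
relative to plume fluctuation, instantaneous activation is the default.
Background odor is constant in space and time up to zero-mean Gaussian
variation (clamped at zero, redrawn per CFD step) and is applied at the
sensor as added motif concentration, not as a dye channel.

## The circuit

The full-scale architecture is fixed by its counts: 1,024 sensors pooled
4 : 1 by 256 mitral units; 256 feedforward interneurons (fan-in 16 —
their count and fan-in are configurable, as no canonical value exists);
4,096 cortical neurons × 8 branches × (16 E + 4 I) = 655,360 cortical
synapses; 16 motor units × 256 random cortical afferents. The desk preset
(`network_config_desk()`) keeps every ratio at 512 cortical neurons and
256 sensors.

Units are rate-style: graded sensor and mitral activations, binary
interneuron, cortical and motor outputs; there is no membrane-potential
integration — PSPs are additive with a box-car persistence of `D`
timesteps per synapse class, the simplest shape with one parameter.
Every stage reads only the previous timestep's output of its presynaptic
stage, and the direct mitral→cortex path is delayed one extra step so
excitation arrives with its matching disynaptic feedforward inhibition;
the result is exactly one timestep per stage and the five-timestep
sensor→motor latency that `measure_latency()` verifies. Ties activate:
activation equal to threshold counts as firing, a fixed convention for
reproducibility.

Branches integrate in one of three modes — thresholded (branch fires at
threshold, soma fires when `n_b` of its branches fire; `n_b` defaults to
2 and is evolvable, as no printed value exists), linear, or sigmoidal
(logistic with evolvable gain; soma thresholds the aggregate). All five
synapse classes carry first-order depression: release `a·R` depletes
`R <- R(1 - U a)` and recovers `R <- R + r_rec (1 - R)` per step, giving
the fixed point `R* = r_rec / (r_rec + U - U r_rec)` under sustained
activation. For graded presynaptic activity the depletion scales with
`a`, which reduces to the binary rule at `a = 1`.

### Homeostatic excitability and calibration

Branch thresholds (all modes) and soma thresholds (aggregate modes) are
homeostatic: a per-unit exponential moving average of activity
(`tau_avg = 200` timesteps) nudges the threshold by `eta = 1e-3` per step
toward the evolvable target rate, clipped to `[1e-4, 50]`. The adjustment
rate and averaging constant are fixed; only the targets evolve. In the
thresholded branch mode the soma's lever is the discrete `n_b`, so soma
rates are governed indirectly — a structural property of that mode.

Because a random genome's initial thresholds are arbitrary, trials open
with a calibration period (`calibrate_network()`): the circuit is driven
with the first sensory sample, raw dendritic drives are recorded once the
PSP pipeline and depression have settled (40 of 56 probe steps
discarded), and the branch threshold — a single global value during
calibration — is set to the drive quantile matching the branch target
rate, after which local homeostasis refines thresholds per branch during
operation. Continuous homeostasis is the default; a freeze flag
(`set_homeostasis()`) reproduces calibration-style frozen operation.

## Motor mapping and behavior

Motor units 1–4 are the left-forward pool, 5–8 left-backward, 9–12
right-forward, 13–16 right-backward (an index-block assignment;
configurable), with forces 1, 2, 4, 8 in index order within each pool —
the size principle. Net tread current = forward sum − backward sum,
scaled by the evolvable gain and clamped to ±127; at gain 1 each tread
spans exactly −15…15, and every value in that range is attainable.

The built-in exploratory behavior classifies each step into one of five
states with a strict priority: REVERSING (zero proximity or an active
1 s reversing dwell) > HIGH (summed concentration ≥ 0.6) > RISING /
FALLING (change over the last 1 s beyond a 0.02 deadband) > LOW. Commands
are surge (15, 15) on RISING, slow advance (4, 4) on HIGH, crosswind
casting (±12 alternating each 0.3 s) on FALLING, a seeded biased random
walk on LOW, and backing (−10, −10) on REVERSING — magnitudes and dwells
are configurable artifact choices in the spirit of surge/cast chemotaxis,
since only the states themselves are canonical. Whether the thresholds
apply per channel or to the summed concentration is not fixed by any
source; the sum is used.

## The closed loop

Per 30 ms CFD step the world samples the sensor position (bilinear, at
the front-center of the chassis by default — the sensor's exact mounting
is configurable), passes the concentrations through the ASCII protocol
round-trip, and hands them to the controller, which advances 4 neural
timesteps — one beta cycle per CFD update, so 10,000 neural timesteps
correspond to 2,500 beta cycles. Routing the in-process path through the
same `SENSE`/`MOTOR` encoding as the socket path (6-decimal fixed-point,
≤ 40 bytes per message) makes the two couplings produce bit-identical
trials rather than merely similar ones. The final substep's motor
activity is the step's command. Trials terminate at the first step inside
the proximity radius of the target source or at `T_max`; results carry
one log row per CFD step.

## Artificial evolution

The genome (schema v1) names 31 bounded parameters: per synapse class a
weight, PSP duration, depression fraction and recovery rate (20), the
branch/soma homeostatic targets, `n_b`, the branch gain, initial branch
and soma thresholds, the interneuron and motor thresholds, the motor
gain, and the two sensor kinetic rates. The set is the package's own
documented choice — no canonical list of the "roughly 50" evolved
parameters exists — and is versioned so it can grow without breaking
stored genomes. The weight bounds are chosen so a random draw's
feedforward excitation/inhibition balance usually leaves the cortex
excitable (16 E vs 4 I per branch): a prior under which random genomes
produce motor activity at all, giving selection something to act on.

Fitness is the time to reach the target's proximity radius; unsuccessful
trials score `T_max` plus the final distance normalized by the world
diagonal, which preserves a selection gradient when nothing reaches the
source. Per-individual evaluation seeds are hashes of (master seed,
generation, index), so results are independent of evaluation order — the
contract that makes generations parallelizable. Operators are tournament
selection, uniform crossover, per-gene Gaussian mutation clipped to
bounds, and elitism 1. The desk defaults (tournament 12 of 16, mutation
probability 0.4, sigma 0.15 of range annealed by 0.95 per generation)
lean deliberately toward exploitation: a 16 × 20 desk run affords only
320 evaluations, a regime closer to a (1+λ) strategy than to a large
diverse GA; they collapse a convex (sphere) landscape by two orders of
magnitude in 50 generations, the package's sanity oracle for the
operator suite. Full-scale runs (populations and generation counts of
100–150) can soften the pressure.

## Study conditions of the desk-scale evolution

The `"chase"` fixture defines the desk evolution world, chosen once as
the package's study conditions: a 70 × 70 grid (1.4 m box), one odorant
channel, a plume source at (0.35, 0.69) m emitting 50 units/s, a steady
wind block carrying the plume +x at a few tenths of a m/s, 150 warm-up
steps before the robot is released 0.24 m downwind facing the source, a
0.12 m proximity radius, and `T_max = 4.2` s at `dt = 0.03` (the robot
covers up to 0.25 m in that time, against a 0.12 m start-to-radius gap).
The
grid omits molecular viscosity and dye diffusivity (both physically
negligible at these scales and timescales; the semi-Lagrangian scheme's
numerical mixing dominates regardless) and runs 8 projection sweeps,
interactive fidelity. The evolved network is the 512-neuron desk preset.

Desk-scale runs demonstrate that selection on time-to-source fitness
improves the best individual over the initial generation's median under
elitism. They do not reproduce full-scale results — hundred-member
populations over a hundred generations, multi-plume discrimination
against background — and improvements at this scale are correspondingly
modest: early generations mostly exploit wiring asymmetries in the motor
readout rather than discovering full plume-tracking policies.

## What the synthetic worlds do and do not show

The fixtures (`three-plume`, `two-plume-room`, `corridor`, `chase`) exercise
multi-plume layouts, internal boundaries, wind sources and closed-loop
termination, and every generator is deterministic under its seed, so all
results in the test suite are exactly reproducible. They emulate
enclosed-room plume dispersal at interactive fidelity; they do not
emulate 3-D turbulence, intermittency statistics of natural plumes,
sensor drift or slip of a physical robot. Passing tests therefore
establish the correctness and reproducibility of the models as specified
— not field performance of an odor-seeking robot.

## Numerical and testing choices

Tolerances follow the quantity's numerics: exact identities (half
activation at `C = K/d`, structural counts, protocol parses) are asserted
exactly; converged fixed points (depression, kinetics) at 1e-6–1e-9;
stochastic long-run rates (homeostasis) within 10–20% of target with
explicit sampling allowances. Problem sizes in the suite are chosen for
desk-scale runtimes: 16 × 16 oracle grids for projection accuracy, a
64-neuron circuit for stepping semantics, 10,000-step homeostasis runs,
five seeded 16 × 20 evolution runs. Determinism is tested as bit-identity
(trajectories, fields, histories), which is why every stochastic entry
point takes an explicit seed and restores the caller's RNG state.
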