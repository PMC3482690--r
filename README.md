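# plumebot

**plumebot** is an integrated platform for studying *olfactorimotor*
control: how a neural circuit that smells can steer a body whose movement,
in turn, stirs the odor world it is smelling. It targets researchers in
computational neuroscience and neurorobotics who want a closed
sensorimotor loop — not a pre-computed plume — cheap enough to run tens of
thousands of trials for evolutionary parameter search.

The package provides, as composable parts:

* **An interactive plume world.** A 2-D stable-fluids solver (implicit
  diffusion, semi-Lagrangian advection, pressure projection — the
  unconditionally stable scheme used in interactive fluid simulation)
  carries up to *K* odorant "dye" channels over a 140 × 140 grid at 30 ms
  per step, with wind sources, first-order evaporation, internal
  boundaries, and perturbation of the flow by the moving robot: at every
  cell along the robot's leading edge a force equal and opposite to the
  local flow vector is injected each step.
* **A motif-based chemistry.** Odorants are vectors of degrees
  *d*<sub>α</sub> ∈ [0, 1] over 10 abstract molecular motifs; sensor *i*
  binds motif α with affinity 1/*K*<sub>iα</sub>. A single-motif odorant at
  concentration *C* activates the sensor as
  *A* = *C·d* / (*C·d* + *K*), so *A* = 0.5 exactly at *C* = *K*/*d*;
  mixtures combine receptor occupancies *S* = Σ<sub>α</sub>
  *m*<sub>α</sub>/*K*<sub>iα</sub> as *A* = *S*/(1 + *S*). Finite-rate
  kinetics d*A*/d*t* = *r*<sub>f</sub>(*Ā* − *A*) − *r*<sub>β</sub>*A* are
  available; instantaneous activation is the default operating mode.
* **A five-stage circuit.** 1,024 sensors → 256 mitral relay units
  (disjoint clusters of 4) → feedforward inhibitory interneurons and a
  cortical array of 4,096 pyramidal neurons, each with 8 independent
  dendritic branches receiving 16 excitatory and 4 inhibitory inputs (160
  afferents per neuron; 655,360 cortical synapses) → 16 motor units with
  256 random cortical afferents each. Branches are thresholded units
  (linear and sigmoidal modes are provided); all five synapse classes
  carry additive PSPs with evolvable duration, first-order depression and
  recovery; branch and soma excitability is homeostatically regulated
  toward evolvable target rates. Activity traverses sensor → motor in
  exactly five simulation timesteps.
* **Size-principle motor pools.** The 16 motor units form four pools
  (left/right × forward/backward) with forces 1, 2, 4, 8; backward pools
  encode negative values, and the signed per-tread current (an 8-bit
  integer, spanning ±15 at gain 1) drives a differential-drive robot with
  velocity-proportional friction and collision proximity sensing.
* **Controllers and coupling.** A built-in five-state exploratory behavior
  (low / high / rising / falling concentration, plus a collision-triggered
  reversing mode), the neural controller, and a world↔brain ASCII socket
  protocol (`SENSE c1 c2 c3` / `MOTOR l r`, a few tens of bytes per step;
  4 neural timesteps per 30 ms CFD step — one beta cycle).
* **Artificial evolution.** A genetic algorithm (tournament selection,
  uniform crossover, clipped Gaussian mutation with an annealing schedule,
  elitism) over a documented 31-parameter genome, minimizing
  time-to-source fitness over closed-loop trials, with
  scheduling-independent per-individual seeds, checkpointing, and tidy
  history output.

## Worked example

Release the robot downwind of a plume and let the built-in five-state
behavior track it to the source:

```r
library(plumebot)

scn <- generate_fixture("chase", seed = 1, scale = "desk")
scn$max_duration <- 20                       # give the cast time to work
ctrl <- behavior_controller(scn$behavior, dt = 0.03)
res <- run_trial(scn, ctrl, seed = 42)
res
#> <trial_result> chase: reached source, time 7.53 s, final distance 0.120 m, 0 collision(s)
glance(res)
#> # A tibble: 1 × 7
#>   reached time_to_source final_distance collisions n_cfd_steps n_neural_steps
#>   <lgl>            <dbl>          <dbl>      <int>       <int>          <int>
#> 1 TRUE              7.53          0.120          0         251           1004
```

The robot surged upwind whenever concentration rose, cast crosswind when
it fell, and entered the 0.12 m proximity radius of the source after
7.53 s; 251 CFD steps (beta cycles) drove 1,004 neural timesteps at the
4 : 1 cadence. `tidy(res)` returns the per-step trajectory,
`tidy(res, "concentrations")` the per-step odor trace, and
`autoplot(res)` draws them.

Evolving a neural controller instead:

```r
hist <- run_evolution(evolution_config(seed = 11),
                      generate_fixture("chase", seed = 1, scale = "desk"),
                      network_config_desk())
glance(hist)     # best fitness vs the initial generation's median
autoplot(hist)   # per-individual fitness and the best-so-far envelope
```

A thin command-line front-end over the same functions lives at
`inst/scripts/plumebot.R` (`simulate`, `evolve`, `fixtures`, `serve`).

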