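# critppi

Lattice Monte Carlo simulation of protein-protein interaction (PPI)
networks solvated by a lipid membrane near its liquid-liquid miscibility
critical point.

## The problem

Animal-cell plasma membranes sit close to a miscibility critical point:
lipids transiently demix into liquid-ordered (lo) and liquid-disordered
(ld) domains whose size is set by the distance to criticality. Many
signaling proteins partition preferentially into one phase — activating
kinases often into lo, deactivating phosphatases into ld — so the membrane
decides *who meets whom*. `critppi` is for quantitative membrane
biophysicists who want to simulate how perturbations of membrane
criticality (temperature, tie-line composition, component size,
partition-modifying reactions such as palmitoylation) reshape the output
of contact-driven interaction networks.

## The model

* **Membrane**: an `L x L` periodic Ising lattice, spins `s = ±1` for
  lo/ld-preferring lipids, `H_mem = -J Σ s_u s_v` over nearest-neighbour
  lipid pairs. Temperature is the rescaled `τ = T / Tc` with
  `Tc = 2J / ln(1 + √2)` (bare membrane); composition is the magnetization
  `m = <s>`, fixed exactly by conserved-order-parameter (Kawasaki) spin
  exchange.
* **Proteins**: disk inclusions (footprint `dx² + dy² ≤ r²`) whose
  boundary sites carry a uniform spin `b = ±1` (the domain preference,
  possibly state-dependent) coupled to adjacent lipids with `J_int`.
  Disks diffuse by detailed-balance translation moves.
* **Reactions**: when an actor touches a substrate (four-adjacency), the
  substrate's state flips to the rule's product state at a fixed rate.
  Effective rates inherit the solvent's critical behaviour through contact
  frequencies. Partition-switching rules also flip `b` — instantaneously,
  violating detailed balance, which can drive far-from-equilibrium
  "pocket" domains.
* **Response curves**: steady-state active-target fraction `f_A` versus
  `τ` is summarized by the generalized logistic fit
  `f_A(τ) = (R−L)/2 · tanh((τ−τ₀)/(2Δτ)) + (R+L)/2`;
  the growth width `Δτ` measures how sharp a criticality sensor the
  network is.

## Worked example

```r
library(critppi)

net <- static_partitioning_network()   # ld-preferring activator,
                                       # lo-preferring inactivator + target
sign_predict(net)$prediction
#> [1] 1      # all pathway sign products positive: activity rises with tau

cfg <- sim_config(net, L = 64, tau = 1.05, sweeps = 20000, seed = 3)
res <- run_simulation(cfg)
res
#> <sim_result> L=64 tau=1.05 m=0, 20000 sweeps (201 records)
#>   steady-state target activity f_A = 0.3322

# temperature scan and logistic fit (reduced scale)
scan <- run_scan(sim_config(net, L = 64, sweeps = 30000, seed = 202),
                 axis = "tau", values = seq(0.85, 1.4, length.out = 8),
                 replicates = 3, seed = 202)
fit_logistic(scan$value, scan$f_A)
#> <logistic_fit> L=0.0861 R=0.4928 delta_tau=0.2081 tau0=1.0465 (converged: TRUE)
```

The fitted inflection `τ₀ ≈ 1.05` sits just above the bare critical point:
target activity responds most steeply to the membrane's distance from
criticality exactly where domain sizes change fastest. The
partition-switching variant (`partition_switching_network()`) plus
`detect_pockets()` reproduces the kinetically trapped high-activity
pocket domains; `cross_correlation()` quantifies how activators approach
and inactivators retreat from targets as `τ` grows.

A thin command-line front end (`inst/cli/memsim.R`) exposes
`run` / `scan` / `fit` / `analyze` subcommands over YAML network files;
bundled networks live in `inst/extdata/`.

## Package layout

| where | what |
|---|---|
| `R/lattice.R` | Ising membrane: initialization, Hamiltonians, Kawasaki sweeps |
| `R/inclusions.R` | disk rasterization, translation moves, contacts |
| `R/network.R` | network spec, YAML I/O, diagrammatic sign predictor |
| `R/simulation.R` | scheduler, traces, parameter scans |
| `R/analysis.R` | `f_A`, logistic fits, cross-correlations, pocket detectors |
| `R/oracle.R` | exhaustive Boltzmann enumeration for sampler validation |
| `src/engine.cpp` | the Monte Carlo hot loops (Rcpp) |
| `vignettes/` | model assumptions, parameter choices, limitations |
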