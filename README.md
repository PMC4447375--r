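# sleepsyn

Simulation and analysis of sleep-dependent synaptic plasticity in two
network models, for computational neuroscientists studying how slow-wave
sleep (SWS), REM sleep and their transition reshape synaptic weight
patterns.

## The models

**Model 1 — stochastic binary network with Hebbian rescaling.** A fully
connected excitatory network of N binary units updated every 4 ms. The
total current of unit *i* is

    I_i = w_ie * e_i + (1/(N-1)) * sum_j w_ij * v_j

with external spikes `e_i`, and states are drawn from the adjusted sigmoid
`P(v_i = 1) = 1 / (1 + exp(K_t - K_s I_i))` with `K_t = 6`, `K_s = 11`.
Synchronous firing within a bin potentiates a synapse by
`C_p J(w) dt` with `J(w) = exp(-w) - exp(-1)` (weight-dependent, zero at
w = 1), and a presynaptic spike without a postsynaptic one depresses it by
`C_d (0 - theta) dt` (`C_p = 6.25/s`, `C_d = 0.021/s`, `theta = 1`).
Sleep-dependent LTP adds a Gaussian bonus triggered 30 s after a selected
REM onset, peaking 30 min later, with a per-synapse gain `Cieg` computed
either from pairwise spike synchrony during SWS epochs (LTP1 family: full
episode, last 30 s, or last 30 s of SWS plus first 30 s of REM) or from
the angle of the weight trajectory at the SWS/REM transition (LTP2
permissive / restrictive). Weight-pattern metrics: net weight change
`M_dw`, similarity index, Spearman rank restructuring, and the
`|dw/dt| <= 0.00025` steady-state criterion.

**Model 2 — hippocampo-cortical LIF network with sleep-modulated STDP.**
45 leaky integrate-and-fire neurons, each receiving 200 plastic input
synapses and global feedback inhibition; inputs encode two memories in
alternating 125 ms windows (active units 20 Hz, inactive 10 Hz, halved
during sleep). Pairwise STDP (`tau = 20 ms`, `C_p = 3.2 nS`,
`C_d = 0.03`, noise sd 0.015) is modulated during sleep by a factor
`gamma_sleep` (potentiation weakened, depression strengthened), embossing
LTP adds a Gaussian bonus (peak 405 s, SD 45 s, 0.05 nS integral) shaped
by a randomly chosen other neuron's pre-sleep weights (`theta`, scaled by
`kappa_sleep`), and every step ends with multiplicative normalization to a
per-neuron mean weight of 0.25 nS. Memory selectivity, switch proportion
`T_S`, LTP-hit proportion `T_H` and a 200-shuffle surrogate test quantify
what sleep did to the memory structure.

All inputs are synthetic and generated in-package: Poisson and correlated
spike rasters, hypnograms calibrated to rat sleep architecture (mean SWS
episode ~87 s; 91.6% of REM-to-REM intervals under 30 min),
state-conditioned rasters obeying the empirical rate ordering
WK > REM > SWS and synchrony ordering WK > SWS > REM, and the two-memory
window protocol. A CSV importer/exporter accepts user rasters and
hypnograms.

## Worked example

```r
library(sleepsyn)

# Rate-dependent rescaling: feed 50 binary neurons independent Poisson
# spikes and run to the steady-state criterion.
cfg <- model1_config(N = 50)
lo <- run_model1_to_convergence(cfg, rate = 5, seed = 42)
hi <- run_model1_to_convergence(cfg, rate = 10, seed = 42)
c(low = lo$mean_w, high = hi$mean_w)
#>       low      high
#> 0.4025918 0.6059215
```

Low-rate drive (5 Hz, SWS-like) converges below the 0.5 initialization
midpoint — net synaptic downscaling — while 10 Hz (WK-like) converges
above it: the steady state of the weight distribution tracks the input
rate. The analysis drivers under `analysis/` reproduce the full studies:

```sh
Rscript analysis/01_generate_inputs.R     # calibrated synthetic inputs
Rscript analysis/02_model1_rate_sweep.R   # 3-40 Hz convergence sweep
Rscript analysis/03_model1_sleep_ltp.R    # five LTP variants vs no-LTP
Rscript analysis/04_model2_sleep_grid.R   # gamma x kappa selectivity grid
Rscript analysis/05_report.R              # aggregate results/summary.json
```

Each script writes its tables under `results/` and prints a digest of
what it found.

## Package layout

- `R/`, `src/` — generators, both simulation cores (Rcpp), LTP variants,
  weight and memory metrics, sweep orchestration.
- `analysis/` — numbered study drivers (see above).
- `vignettes/sleep-plasticity-models.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical conventions, and what the
  synthetic data do and do not emulate.
- `tests/testthat/` — unit, property and acceptance suites.
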