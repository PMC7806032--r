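# perchsense

Where should a balance sensor sit on a perched, compliant biped? Birds have
two candidate answers: the vestibular system in the head and the
lumbosacral organ (LSO) between the hips. `perchsense` is an R package for
comparing those sensor placements quantitatively. It simulates a
lumped-parameter perched body — feet attached to a moving platform,
spring-loaded legs carrying a torso mass, a neck of selectable stiffness
carrying a head mass — excited by thousands of random center-out-and-back
platform displacements, and analyses the resulting foot, hip and head
3-axis accelerometer traces:

* **Effective stiffness** from the spectral resonance of head acceleration,
  `K = m f²` with `f` the frequency of maximal Welch power.
* **Sensing delays** from the lag maximizing the normalized
  cross-correlation between the foot trace and the hip or head trace.
* **Foot-state estimation**: how much of the foot acceleration a low-order
  linear observer can reconstruct from hip, head, or fused sensing. Models
  `x(k+1) = A x(k) + B acc_sensor(k)`, `acc_foot(k) = C x(k) + D acc_sensor(k)`
  are fitted by ordinary MOESP subspace identification and scored with the
  variance-accounted-for statistic,
  `%VAF = 100 (1 − var(acc_foot − âcc_foot) / var(acc_foot))`.
* **Uncertainty** via bootstrap resampling of random analysis windows,
  summarized as median (IQR), with Welch t-tests between conditions.

The fitting core is the classic R modelling idiom: `moesp()` returns a
classed object with `print()`, `summary()`, `coef()`, `predict()`,
`fitted()` and `residuals()` methods.

## A worked example

```r
library(perchsense)

# one trial: high-stiffness neck, 10 mm perturbation sphere, 300 moves
rec <- run_trial("Trial_HS_10", n_moves = 300, seed = 11)
rec
#> Sensor recording [Trial_HS_10]: 150000 samples at 1000 Hz (150.0 s)
#>   channels: foot, hip, head (3-axis, m/s^2); noise sd 0.05

# how long does a platform perturbation take to reach each sensor?
round(sensing_delays(rec, "hip"), 3)
#>     x     y     z
#> 0.020 0.015 0.018
round(sensing_delays(rec, "head"), 3)
#>     x     y     z
#> 0.060 0.054 0.058

# reconstruct foot acceleration from hip sensing with an order-3 model
est <- estimate_foot_acc(rec, "hip", order = 3, s = 10,
                         train_samples = 4000)
est
#> Foot-acceleration estimate from hip sensing (4000 samples)
#>   pooled VAF 73.52% (per axis: x 74.88, y 72.27, z 73.14)
```

The hip sensor feels the perturbation roughly three times sooner than the
head sensor (the signal must also traverse the compliant neck), and an
order-3 observer driven by hip acceleration recovers about 74% of the foot
acceleration variance on this configuration; the head-driven observer
recovers 47% (`estimate_foot_acc(rec, "head", ...)`).

`run_experiment(experiment_config("fast", master_seed = 1))` runs the full
grid — four sphere radii × two neck stiffnesses — with stiffness, delay and
VAF bootstraps and the between-condition comparisons, and `report()` prints
the medians (IQR), p-values and which qualitative sensor-placement findings
the run reproduces. A thin command-line wrapper is installed under
`inst/exec/perchsense.R` (`simulate`, `run`, `report` subcommands).

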