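# reflexop

Closed-loop operant conditioning of stimulus-evoked muscle responses, in R.

## What this is for

Protocols that condition the soleus H-reflex — the electrically elicited
analog of the spinal stretch reflex — deliver a tibial-nerve stimulus only
when the participant holds background EMG inside a target range, measure
the evoked M-wave (*reference*) and H-reflex (*target*) on every trial,
and reward trials whose H-reflex falls on the right side of a criterion
threshold. Down-conditioning this pathway can improve walking in people
with spastic gait after incomplete spinal-cord injury.

`reflexop` is the computational engine of such a system, for researchers
who want to study, prototype or verify the protocol logic without
hardware:

* **Background level**: mean rectified value of causally high-pass-filtered
  EMG in a trailing sliding window, streaming-safe (block-by-block
  processing is bit-identical to one-shot).
* **Stimulation gate**: a stimulus fires only after the background EMG of
  both muscles has stayed in range continuously for the hold duration
  (2 s) and at least the minimum interval (5 s; 3 s in stimulus-test
  mode) has passed since the previous stimulus.
* **Response quantification**: stimulus-locked epochs; peak-to-peak or
  mean-rectified size in half-open latency windows (defaults:
  M-wave [6, 23) ms, H-reflex [28, 45) ms post-stimulus).
* **Run analysis**: pooled recruitment curves with M_max/H_max (M-wave
  rises then saturates; H-reflex rises then falls), response-size
  distributions, percentile criteria (default: 66th percentile;
  down-conditioning success ⇔ size ≤ threshold), cumulative success
  rates, and retrospective M-wave constancy checks.
* **Sessions**: baseline (RC, 3×75 control trials, RC), conditioning
  (RC, 20 control trials, 3×75 training trials, RC) and follow-up
  templates; sequential never-overwriting run files named
  `YYYYMMDD-HHMM_<ID>_<MODE><NN>`; three-hour session continuation;
  append-only logs; full protocol plans (6 baseline + 24–30 conditioning
  + 4 follow-up sessions).
* **Virtual participant**: band-limited background EMG with fluctuating
  drive, logistic M-wave recruitment `M_max·σ(s_m(I−i50_m))`, unimodal
  H-reflex recruitment `e·H_max·σ(s_h(I−i50_h))·(1−σ(s_c(I−i_coll)))`,
  trial-to-trial noise, and reinforcement-driven plasticity of the
  excitability state `e` — so the entire loop runs end to end in software.

## Worked example: one conditioning session, in silico

```r
library(reflexop)

p   <- virtual_participant()        # 6 mV M_max, 3 mV H_max, plasticity on
cfg <- closed_loop_config()         # 2 s hold, 5 s interval, P66, down
out <- run_closed_loop(p, session_template("conditioning"), cfg, seed = 42)

runs <- out$sessions[[1]]$runs      # RC, CT20, TT75, TT75, TT75, RC

build_recruitment_curve(runs[[1]]$trials, runs[[1]]$trials$intensity_mA)
#> <recruitment_curve> 19 pooled points (pool 4, peak_to_peak); M_max 6.405 mV, H_max 2.734 mV

compute_distribution(runs[[2]]$trials$target)
#> <response_distribution> n 20, mean 2.783, median 2.763 mV; P66 lines: up 2.634, down 2.901

out$sessions[[1]]$criteria[[2]]     # adopted from the control run
#> <conditioning_criterion> down-conditioning, threshold 2.901 mV (P66)

tt3 <- runs[[5]]                    # final training run
mean(tt3$trials$target)
#> [1] 1.163727
tail(success_rate(tt3$trials$success), 1)
#> [1] 98.66667

build_recruitment_curve(runs[[6]]$trials, runs[[6]]$trials$intensity_mA)
#> <recruitment_curve> 19 pooled points (pool 4, peak_to_peak); M_max 6.679 mV, H_max 1.032 mV

assess_reference_stability(tt3$trials$reference, m_amplitude(20, p))
#> <stability_report> run mean 3.956 mV vs nominal 4.009 mV (-1.3%): within tolerance
```

Reading the numbers: the opening recruitment curve recovers the
participant's programmed maxima (M_max 6 mV plus measurement noise; the
H-curve's true peak is ≈2.7 mV at ≈20 mA). The 20-trial control run sets
the down-conditioning threshold at its 66th percentile (2.901 mV). Across
three training runs the reinforced virtual participant lowers its H-reflex
(final-run mean 1.16 mV), while the M-wave — the check that effective
stimulation stayed constant — moves only −1.3%. The closing recruitment
curve shows the conditioned state: H_max down, M_max unchanged.

Plots: `plot_recruitment_curve()` and `plot_distribution()` render the
two standard analysis panels.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/reflexop.R simulate-protocol --sessions conditioning --seed 3 --out-dir data
Rscript inst/cli/reflexop.R analyze data/<session>/<run>.rds --percentile 66 --direction down
```

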