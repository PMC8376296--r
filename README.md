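# cuevigor

Analysis of how cue-evoked neuronal firing encodes the vigor of
reward-seeking locomotor approach, for electrophysiologists working with
operant discriminative-stimulus (DS) tasks: freely moving animals, head
tracking from two LEDs at 30 frames/s, per-neuron spike trains, and
unpredictable reward-predictive cues that trigger approach to a lever.

The package implements the complete analysis chain:

1. **Movement segmentation.** A locomotor index per frame,
   `LI_t = SD(d_{t-4}, ..., d_{t+4})` with `d_A` the head displacement
   between frames `A-1` and `A`; onset/offset thresholds from a 3-Gaussian
   mixture fitted to each session's LI distribution (onset = density
   intersection of components 2 and 3; offset = intersection of 1 and 2);
   movement onsets as runs of 4 supra-threshold frames after 1 s of
   stillness (70% of 30 frames below the offset threshold).
2. **Trial kinematics.** The standard locomotor descriptor set per
   cue-evoked approach (radial and angular velocity with respect to the
   lever, speed statistics, path length and efficiency, turn efficiency,
   heading change, latencies) plus behavioral-state variables at cue onset
   (lever distance and bearing, times since reward/press/cue).
3. **Excitation detection.** 20-ms peri-cue bins; a neuron is cue-excited
   when ≥ 3 consecutive bins in 40–180 ms exceed a 99.9% confidence
   criterion built from the 1-s pre-cue baseline; Z-scored window rates.
4. **Regressor selection.** Squared-multiple-correlation filtering
   (SMC > 0.8 dropped), Kaiser's criterion on correlation eigenvalues,
   maximum-likelihood factor analysis with varimax rotation, and rep
   scores (highest loading minus the signed sum of the others) to pick one
   representative per factor plus weakly loading "independent" variables.
5. **Encoding model.** Per-neuron Poisson GLMs,
   `ln E[Y] = b0 + b1 x1 + ... + bn xn`, on correct still-at-cue DS
   trials; effect sizes as the interdecile-range firing difference
   `IFD = (exp(b * IDR) - 1) * 100%`; population one-sample t tests with
   Holm correction per response window (40–400, 40–180, 180–400 ms);
   cross-subject ANOVA.
6. **Epoch comparison.** For infusion sessions, per-neuron response
   Z-scores in the 45 min before (Q1) and after (Q2) the infusion,
   regression of Q2 on Q1, and t tests of the slope against 0 and 1.
7. **Synthetic sessions.** A generator producing full session bundles
   (tracking CSV, event log, spike trains, manifest) with exported ground
   truth: exponential cue scheduling (mean ITI 30 s), three-state roaming
   behavior, curved brisk approaches, 1.5-mm tracking noise, and
   inhomogeneous-Poisson neurons whose two-phase evoked response
   (40–180 / 180–400 ms) has a trial gain log-linearly coupled to maximum
   radial velocity, path efficiency, and lever distance.

## Worked example

```r
library(cuevigor)

gs  <- generate_session(sim_config(n_neurons = 40), seed = 42)
res <- analyze_session(gs$bundle)

print(res$thresholds)
#> <vp_thresholds> 3-Gaussian mixture of locomotor index
#>       weight   mean     sd
#> still 0.6156 0.9091 0.2453
#> slow  0.1437 2.1985 0.8163
#> move  0.2407 5.9798 2.6135
#>   offset 1.511 mm < onset 3.424 mm (n = 100000, loglik = -143524.3)

res$summary[, 1:6]
#>   cue_type n_presented n_responded response_ratio latency_mean_s latency_sd_s
#> 1       DS         130         115         0.8846           2.89        5.592
#> 2       NS         117           8         0.0684           1.22        0.743

subset(res$population, window == "overall",
       c(regressor, n, mean_ifd, t, p_holm, significant))
#>                   regressor  n mean_ifd      t   p_holm significant
#> 1       radial_velocity_max 26  11.6621  3.186 0.030777        TRUE
#> 2           move_duration_s 26  -0.0136 -0.210 1.000000       FALSE
#> 3       angular_velocity_sd 26  -2.2866 -0.968 1.000000       FALSE
#> 4           path_efficiency 26  16.7144  4.767 0.000681        TRUE
#> 5    net_heading_change_rad 26   0.7739  1.996 0.341743       FALSE
#> 6           turn_efficiency 26  -0.0251 -0.856 1.000000       FALSE
#> 7  movement_onset_latency_s 26   1.6692  1.393 0.703539       FALSE
#> 8         lever_distance_mm 26  -7.3736 -3.027 0.039641        TRUE
#> 9       time_since_reward_s 26   3.5956  1.628 0.580124       FALSE
#> 10         time_since_cue_s 26  -7.8087 -3.759 0.008255        TRUE
```

The session was generated with positive couplings of the evoked gain to
maximum radial velocity and path efficiency and a negative coupling to
lever distance. The population table recovers exactly that: firing
increases by ~12% across the interdecile range of approach speed and ~17%
across that of path efficiency, and decreases by ~7% across the range of
starting distance, each Holm-significant over the 26 cue-excited neurons.
The remaining rows are null regressors; the significant `time_since_cue_s`
row in this single small session is an example of the feature-measurement
leakage discussed in the methods vignette — regressors carrying no
generative coupling can acquire small population-level pseudo-effects
because all simultaneously recorded neurons share one design matrix.

Mean detected DS latency (2.89 s) exceeds the generative ~1.3 s because a
minority of trials miss the true movement onset and pick up a later bout;
the vignette quantifies this.

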