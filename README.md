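# vcgscar

Rate-dependent vectorcardiogram (VCG) analysis for locating ventricular
scar, aimed at cardiac electrophysiology modellers and biomedical signal
analysts studying non-ischaemic dilated cardiomyopathy (NICM).

Patchy fibrotic scar slows electrical conduction, and the slowing grows at
rapid pacing as partially refractory tissue lags further behind. `vcgscar`
asks whether that signature is readable non-invasively from the 12-lead
ECG: it simulates ventricular depolarisation at a slow (600 ms) and a
rapid (300 ms) basic cycle length for parameterised scars, reconstructs
the VCG, and quantifies how the QRS loop changes with rate.

The chain, end to end:

1. **Forward model** — an idealised two-chamber shell of `n` equal-mass
   patches, each an elementary dipole; the net dipole is
   `d(t) = Σᵢ sᵢ ûᵢ w(t − tᵢ)` with Gaussian waveform `w` and shortest-path
   activation times `tᵢ` from endocardial root sites. Scar is a box in
   universal ventricular coordinates (φ, ρ, z) with a dense core, boundary
   zone and low-density rim (removal probabilities 0.9 / 0.75 / 0.6);
   surviving scar conducts slowly, and only at the rapid rate is the
   slowing amplified. Leads are generated through the pseudo-inverse of
   the Kors matrix, so `kors_transform()` recovers `d(t)` exactly.
2. **VCG metrics** — QRS delimited where the spatial velocity
   `√(vx² + vy² + vz²)` of the filtered VCG exceeds 0.15 of its maximum;
   then QRS duration, signed component areas combined as
   `QRSarea = √(Ax² + Ay² + Az²)`, magnitude-weighted average azimuth and
   elevation (WAA, WAE), mean/maximum dipole magnitudes, and the dipole
   vectors at QRS start, mid and end.
3. **Rate comparison** — paired slow/fast deltas: percentage changes
   (ΔVCGmax, ΔQRSarea, ΔV̄CG), ΔQRSd = QRSd_slow − QRSd_fast, and angle
   differences between corresponding dipole vectors (dTVCGmean, dTVCGmax,
   dTQRSstart, dTQRSmid, dTQRSend).
4. **Localisation** — per-metric ROC/AUC (positive class = LV free wall,
   orientation never flipped) and random forests (Gini, unrestricted
   depth, 5-fold or leave-one-out CV, seed 42) answering two independent
   binary questions: is the scar in the LV free wall; is it in the septum.

## Worked example

A large LV free-wall scar, one paired two-rate experiment:

```r
library(vcgscar)
scar <- scar_definition("lv_free_wall")
pair <- list(slow = simulation_scenario(600, scar, seed = 8, duration = 500),
             fast = simulation_scenario(300, scar, seed = 8, duration = 500))
ecgs <- simulate_pair(pair)
metrics <- lapply(ecgs, function(e) vcg_metrics(kors_transform(e)))
metrics$slow
#> <vcg_metrics> QRSd 120.0 ms | QRSarea 154.2 mV.ms | WAA -4.0 deg WAE 92.3 deg | |VCG| mean 1.851 max 4.819 mV @ 56.0 ms
metrics$fast
#> <vcg_metrics> QRSd 93.0 ms | QRSarea 184.6 mV.ms | WAA -8.6 deg WAE 97.2 deg | |VCG| mean 2.201 max 5.111 mV @ 56.0 ms
compare_rates(metrics$slow, metrics$fast)
#> <rate_comparison>
#>   d_vcg_max         6.057
#>   d_qrsd           27.000
#>   d_qrs_area       19.719
#>   d_vcg_mean_mag   18.945
#>   d_waa             4.598
#>   d_wae             4.931
#>   d_t_vcg_max       0.000
#>   dt_vcg_mean      11.250
#>   dt_vcg_max        5.221
#>   dt_qrs_start      2.569
#>   dt_qrs_mid        7.994
#>   dt_qrs_end       25.029
```

Reading it: at the rapid rate the scar's slowed, mass-depleted tail falls
below the QRS detection threshold, so the measured QRS *shortens* by 27 ms
(`d_qrsd = +27` under the slow − fast convention) while the area and mean
dipole magnitude rise; the end-of-QRS dipole rotates by 25°. A scar-free
pair returns exactly zero in every field — the control is rate-neutral by
construction, and physiological beat-to-beat jitter is modelled separately
(`jittered_control_pairs()`).

The full study is one call: `run_pipeline(default_pipeline_config())`
simulates the default cohort (30 scarred pairs spanning φ/ρ/z ranges and
densities in both locations, plus control), writes every intermediate
artifact (ECG traces, per-scenario metrics JSON, the feature table, ROC
table, forest reports, a run manifest), and is exactly reproducible from
its seeds. A thin CLI with the same stages lives at `inst/cli/vcgscar.R`
(`run-all`, `simulate`, `metrics`, `roc`, `forest`).

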