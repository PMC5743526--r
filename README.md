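# mudick

Quantitative susceptibility mapping (QSM) estimates tissue magnetic
susceptibility χ (in ppm) from gradient-echo MRI phase. The inversion is
ill-posed where the dipole kernel

    d(k) = 1/3 − k_z² / |k|²

vanishes (the magic-angle cone at ≈54.7° from B0): direct inversion (TKD)
streaks, and magnitude-edge L1 methods (MEDI-type) suppress streaks but
under-estimate small veins whose contrast the magnitude image does not
carry.

`mudick` implements **MUDICK** — *multiple dipole-inversion combination
with k-space segmentation* — for R. k-space is split into three domains:

1. low-frequency and magic-angle domains are solved with a structural L1
   penalty, `½‖M_nMA F(χ′ − χ_l)‖² + λ Σᵢ ‖Mᵢ Gᵢ χ′‖₁`, whose edge
   masks come from an *unregularized* early-stopped pre-estimate χ_s
   (3 CG iterations) rather than the magnitude image;
2. the high-frequency domain is filled directly from χ_s through a
   sigmoid blend `m_H(k) = [1 + tanh{k_cur(|k| − k_th)}]/2`, preserving
   sub-voxel vein contrast.

The package also provides the TKD and MEDI-style baselines, the numerical
vein/nucleus phantom used to validate the method (36 veins spanning
χ ∈ {0.1, 0.2, 0.3} ppm, d ∈ {0.25, 0.5, 0.7} mm, θ ∈ {0, 30, 60, 90}°,
plus four deep-gray nuclei; B0 = 3 T, TE = 20 ms, SNR 30), ROI metrics
(CV, RMSE, regression slope, line profiles) and the parameter-selection
sweeps. Intended users: QSM methods researchers and MRI physicists who
want a reproducible, scriptable reference implementation.

## Worked example

Simulate the scaled phantom (64³ working grid at 0.5 mm), reconstruct
with all three methods, and evaluate the vein ROIs:

```r
library(mudick)

spec <- phantom_spec()                      # scaled study conditions
sim  <- simulate_acquisition(spec, seed = 1)
delta <- vol3d(vol_data(sim$delta) * sim$brain_mask, sim$delta$voxel_size)

cfg  <- recon_config()                      # n_l=50, n_s=3, lambda=10^-1.75, ...
chi_mud  <- mudick(delta, sim$brain_mask, cfg)
chi_tkd  <- tkd_invert(delta, threshold = cfg$tkd_threshold)
chi_medi <- medi_baseline(delta, sim$brain_mask, sim$magnitude)

roi_stats(chi_mud, sim$rois, reference = sim$reference)
```

Output (seed 1):

```
            roi  n        mean         sd   ref_mean       error
1 d0.25_chi0.10 30 0.007056663 0.00909298 0.02583333 0.018776670
2 d0.25_chi0.20 30 0.024286979 0.01053118 0.05166667 0.027379688
3 d0.25_chi0.30 30 0.039607464 0.01443917 0.07875000 0.039142536
4 d0.50_chi0.10 22 0.053829968 0.02083134 0.06988636 0.016056395
5 d0.50_chi0.20 22 0.141035373 0.04169717 0.13977273 0.001262645
6 d0.50_chi0.30 25 0.179604686 0.07619988 0.20400000 0.024395314
7 d0.70_chi0.10 36 0.057970162 0.01352203 0.07986111 0.021890949
8 d0.70_chi0.20 36 0.154226088 0.02946241 0.15972222 0.005496134
9 d0.70_chi0.30 40 0.215485389 0.05791055 0.23250000 0.017014611
```

Reading it: `mean` is the reconstructed susceptibility pooled over the
four same-(d, χ) veins, `ref_mean` the partial-volume ground truth from
the block-averaged model (sub-voxel veins are diluted — the 0.25-mm,
0.1-ppm veins reference at 0.026 ppm), and `error` the absolute
calculation error. The same call on the MEDI-style map gives smaller
means in all nine ROIs (e.g. 0.140 vs 0.215 for the thickest, strongest
veins), the under-estimation MUDICK is designed to avoid.
`cv(chi_mud, sim$rois$vein[["d0.25_chi0.10"]])` (1.29 here) is the
vein-visibility score whose minimum over `n_s` calibrates the
early-stopping count.

Named end-to-end recipes (phantom → reconstruction → metrics → JSON
manifest with checksums) are available through

```r
run_experiment("fig3a_ns_sweep", seed = 1, out_dir = "runs/ns")
run_experiment("tkd_threshold_sweep", seed = 1, out_dir = "runs/tkd")
```

and from the shell via the thin CLI wrapper:

```sh
Rscript inst/cli/mudick-cli.R simulate  --seed 1 --out-dir sim/
Rscript inst/cli/mudick-cli.R reconstruct --method mudick \
    --field sim/delta.nii.gz --mask sim/brain_mask.nii.gz --out chi.nii.gz
Rscript inst/cli/mudick-cli.R experiment --name fig4_artifacts --seed 1 --out-dir runs/fig4
```

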