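# spiralcine

Single-breathhold 3D cardiac cine MRI reconstruction with **through-time
spiral GRAPPA**, plus the forward simulation and left-ventricular (LV)
functional analysis needed to study the method end to end.

## The problem

Standard LV functional CMR acquires one 2D bSSFP cine slice per breathhold;
covering the ventricle takes many breathholds, fatigues patients, and the
variable diaphragm position misregisters slices. A six-fold angularly
undersampled 3D stack-of-spirals bSSFP acquisition collects all dynamic data
in a *single* breathhold (one partition encode per heartbeat) — but the
missing spiral arms must be synthesized. Through-time spiral GRAPPA
calibrates a local interpolation kernel per missing k-space sample from a
short free-breathing, fully sampled calibration scan, exploiting three
independent sources of calibration equations: temporal repetitions
(*through-time*), neighbouring readout points within a trajectory segment
(*through-k-space*), and the partition encodes of the 3D slab
(*through-volume*).

For a missing sample with flanking acquired arms `L`, `R`, readout offsets
`o ∈ {−1, 0, +1}` and channels `c = 1..N`, the synthesis is the linear model

    m(c) = Σ_{a ∈ {L,R}} Σ_o Σ_{c'} w(c; a, o, c') · s(a, o, c')

with weights `w` obtained per (arm gap × missing-offset × 8-point readout
segment) by least squares over all (repetition × partition × segment-point)
replicas of that local sampling pattern in the calibration data — for the
full-scale protocol, 10 × 16 × 8 = 1280 equations against 2 × 3 × N
unknowns per target channel. Filled k-space is gridded by a
density-compensated adjoint non-uniform Fourier transform per partition,
resolved along the slab by an inverse DFT (discarding slab oversampling),
and combined across channels with an adaptive (matched-filter) algorithm.
Threshold segmentation of the reconstructed blood pool yields EDV, ESV,
SV = EDV − ESV, EF = 100·SV/EDV and end-diastolic mass, and
Bland–Altman / Welch / Wilcoxon machinery quantifies agreement between
methods.

Because raw volunteer data is not available, the package ships a dynamic LV
phantom (half-ellipsoidal cavity + incompressible myocardial shell inside a
torso, with analytic volumes), smooth complex coil maps, and the full
stack-of-spirals forward model (free-breathing calibration repetitions with
rigid respiratory displacement, breathheld dynamic frames, complex Gaussian
noise) — so ejection-fraction recovery is an exact-oracle experiment.

## Worked example

```r
library(spiralcine)

p <- sequence_protocol()      # the full-scale 3D protocol
print(p)
#> 3D stack-of-spirals bSSFP cine protocol
#>   TR 4.40 ms, FOV 316 mm, matrix 128, 8/48 arms (R = 6)
#>   12 partitions (+33% oversampling -> 16 encoded) at 8 mm
#>   10 fully sampled calibration repetitions

protocol_report(p)
#> acceleration 6, temporal footprint 35 ms, resolution 2.47 mm,
#> 16 encoded partitions, calibration 34 s, acquired arms 26 ms apart,
#> bSSFP bands every 227 Hz

# desk-scale end-to-end study: simulate, calibrate, reconstruct, analyze
res <- run_pipeline(default_config())
print(res$report)
#> LV functional parameters
#>   EDV 148.1 mL  ESV 54.8 mL  SV 93.3 mL  EF 63.0%
#>   ED phase 1, ES phase 6
print(res$truth)
#> LV functional parameters
#>   EDV 150.0 mL  ESV 55.5 mL  SV 94.5 mL  EF 63.0%
#>   EDM 126.0 g
#>   ED phase 1, ES phase 6
res$nrmse
#> [1] 0.0194   # R = 6 GRAPPA vs fully sampled reconstruction, torso support
```

The six-fold undersampled reconstruction recovers the analytic ejection
fraction essentially exactly (63.0% vs 63.0%) and sits within 2% NRMSE of
the fully sampled reconstruction; zero-filling the same data instead yields
~0.31 NRMSE.

A thin command-line wrapper is installed at `exec/spiralcine`
(`protocol-report`, `design-trajectory`, `simulate`, `calibrate`,
`reconstruct`, `analyze`, `run`), all driven by a YAML configuration and a
seed; see `vignettes/through-time-spiral-grappa.Rmd` for the methods
account.

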