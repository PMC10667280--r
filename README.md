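# ifpinn

Voxel-by-voxel estimation of tumour **interstitial fluid pressure (IFP)** and
the full liposome accumulation time course from a **single**
post-administration concentration image.

High IFP is a hallmark of solid tumours: it blocks convective drug delivery
to the tumour core and predicts poor response to chemo- and radiotherapy, but
measuring it directly requires invasive needle probes. Liposomal CT contrast
agents accumulate selectively in tumours (the EPR effect), and the spatial
pattern of that accumulation is shaped by the IFP field. `ifpinn` inverts
that relationship: given one imaged accumulation map and the tissue transport
parameters, it recovers the pressure field that produced it.

## The method

Interstitial liposome concentration obeys the convection–reaction transport
model

```
dC_i/dt = (L_p S / V) (P_v − P_i(x)) (1 − σ) C_p(t)
          + ∇·( f K C_i ∇P_i ) − k_d C_i  (+ D ∇²C_i),
```

with plasma clearance `C_p(t) = a e^{−bt}`. Writing the right-hand side as
`g(C_i, t)` and discretizing the imaging interval `[t1, t2]` with a q-stage
Gauss–Legendre implicit Runge–Kutta scheme, the two measured maps `u1`, `u2`
are expressed through the unknown stage concentrations `k_n(x)`:

```
u1 = k_n − Δt Σ_m a_nm g(k_m, ·)        (n = 1..q)
u2 = k_n + Δt Σ_m (b_m − a_nm) g(k_m, ·)
```

A small tanh network of the voxel coordinates supplies the stages, the
pressure is a per-voxel trainable array inside `g`, and both are trained
(Adam, then L-BFGS, then an exact projected polish of the same objective) to
minimize the mean squared mismatch of the reconstructed snapshots. The
learned stages *are* the accumulation time course; the learned array is the
IFP map, bounded by the microvascular pressure `0 ≤ P_i ≤ P_v`.

The package also contains the full synthetic validation machinery: the
steady pressure equation `∇²P_i = −α²(P_e − P_i)` with its closed-form 1D
oracle, a mass-conserving Crank–Nicolson transport solver, measurement-noise
injection, CT preprocessing (HU → concentration, three-compartment mixture
inversion, plasma fitting from aorta signal), and a sensitivity harness with
bootstrap confidence intervals.

## Worked example

Generate a synthetic tumour under the standard study conditions (10 cm 1D
domain, 2 cm central tumour, snapshots at 0 and 200 h, 2.5% voxelwise noise),
fit the inverse model, and compare with the known truth:

```r
library(ifpinn)

case <- synthetic_tumour_case(nx = 100, noise_level = 0.025, seed = 11)
fit  <- ifp_pinn(case$pair, case$params, case$plasma, q = 20,
                 config = pinn_config(seed = 1))
print(fit)
#> Voxelwise interstitial fluid pressure fit (discrete-time PINN)
#>   grid: 100 voxels (1D), 20 tumour voxels
#>   snapshots at t1 = 0 h, t2 = 200 h; q = 20 stages
#>   mean tumour IFP: 24.85 mmHg (P_v = 25 mmHg)
#>   final loss 4.209e-05; L-BFGS stopped: iteration limit; polish reached tolerance

relative_mse(fit$pressure, case$pressure, case$geom$mask)
#> [1] 5.794517e-06
mean_ifp(fit)                      # mmHg, mean over the tumour mask
#> [1] 24.8451
head(accumulation_curve(fit), 3)   # mean tumour concentration (mgI/cm^3) vs time (s)
#>        time concentration
#> 1     0.000   0.000000000
#> 2  2473.704   0.005089797
#> 3 12970.106   0.020205481
```

The recovered pressure agrees with the ground truth to a relative mean
squared error of ~0.0006% over the tumour (the true mask-mean IFP here is
24.84 mmHg), and the accumulation curve rises
from the zero pre-administration image to the measured final mean. `plot(fit)`
draws the pressure profile and the accumulation curve;
`predict(fit, times)` projects the concentration forward with the learned
pressure.

The sensitivity study and the imaging-time analysis are one call each:

```r
run_sensitivity(sensitivity_cases(c("baseline", "noise_max")),
                replicates = 5, seed = 1)
imaging_time_sweep(case$conc, case$geom, case$conc$times[c(40, 80, 149)],
                   case$params, case$plasma)
```

A thin command-line front end (`inst/cli/ifpinn.R`) exposes `simulate` and
`infer` subcommands over the same functions.

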