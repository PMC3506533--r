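# ls3relax

Backbone dynamics of intrinsically disordered proteins (IDPs) from
multi-exponential autocorrelation analysis, with ¹⁵N relaxation
back-calculation and viscosity-scaled predictions for macromolecular
crowding.

## The problem

NMR spin relaxation (¹⁵N R₁, R₂ and the steady-state ¹H-¹⁵N NOE) reports on
backbone amide dynamics residue by residue. For folded proteins the
model-free framework separates fast internal motion from overall tumbling;
disordered chains have no single tumbling time, and their amide bond-vector
autocorrelation functions — extracted from MD trajectories *without*
removing overall reorientation — decay on several timescales at once.
`ls3relax` implements the forward analysis for that situation:

1. **Multi-exponential model.** The rank-2 autocorrelation of a bond vector
   is fitted to

   C(t) = Σᵢ aᵢ exp(−t/τᵢ),  Σᵢ aᵢ = 1,  n = 2, 3 or 4,

   with nested F-tests choosing the number of terms. For a disordered chain
   the three-term form (the "LS3" decomposition) separates fast librational
   (a₁, τ₁ ~ ps), intermediate segmental (a₂, τ₂ ~ hundreds of ps) and slow
   tumbling-like (a₃, τ₃ ~ ns) motion.

2. **Spectral density and rates.** The analytic cosine transform

   J(ω) = (2/5) Σᵢ aᵢτᵢ / (1 + (ωτᵢ)²)

   feeds the standard dipolar + CSA expressions for ¹⁵N R₁, R₂ and NOE at a
   stated field. Rotating-frame measurements are converted to R₂ through
   the tilted-frame relation R₂ = (R₁ρ − R₁cos²θ)/sin²θ with
   tanθ = B_SL/Δω, and rigid-rotor tumbling times are recovered from R₂/R₁.

3. **Crowding prediction.** Macromolecular crowding raises microviscosity;
   the package predicts crowded-condition rates by multiplying the slow
   correlation times (all but the fastest term) by the factor by which a
   rigid reference protein's tumbling time grows, optionally with a reduced
   fast-motion amplitude.

It also ships seeded synthetic-data generators (multi-exponential ACFs,
Brownian rotational-diffusion and wobble-in-cone vector trajectories,
exponential intensity decays, per-residue parameter ensembles) so every
stage can be tested against known ground truth, plus readers/writers for
xvg-style ACF tables, vector-trajectory text files and intensity-decay CSV.

## Worked example

```r
library(ls3relax)

# ensemble-average LS3 model of a disordered chain
m  <- build_multiexp_model(c(0.37, 0.36, 0.27), c(7, 419, 3400))  # tau in ps
ss <- spin_system(600)  # 600 MHz, r_NH = 1.02 A, CSA = -172 ppm

relaxation_rates(m, ss)
#> R1 = 1.219 s^-1, R2 = 2.216 s^-1, NOE = 0.1238
```

R₂ ≈ 2.2 s⁻¹ and a small positive NOE are typical dilute-buffer values for
a highly flexible chain. Scaling the slow motions by 1.86 — the factor by
which ubiquitin's tumbling time grows in 160 g/L Ficoll 70 (4.3 → 8.0 ns) —
predicts the crowded condition:

```r
crowded <- apply_crowding(m, crowding_transform(1.86))
relaxation_rates(crowded, ss)
#> R1 = 1.203 s^-1, R2 = 3.491 s^-1, NOE = 0.4218
```

R₂ and the NOE rise markedly while R₁ barely moves. Fitting a synthetic
noisy ACF recovers the generating model and selects n = 3:

```r
lags <- c(0:20, seq(25, 100, 5), seq(110, 1000, 10), seq(1050, 20000, 50))
acf  <- gen_multiexp_acf(m, lags, noise_sd = 0.005, seed = 11)
select_model(acf)
#> Multi-exponential fit: n = 3 (requested 3), ss = 0.01223, dof = 502
#>   a1  = 0.3720   tau1  = 6.98124 ps
#>   a2  = 0.3582   tau2  = 422.185 ps
#>   a3  = 0.2699   tau3  = 3405.19 ps
```

Tumbling-time estimation inverts the rigid-rotor forward model:

```r
rr <- relaxation_rates(rigid_model(4300), ss)
estimate_tauc(rr$R1, rr$R2, ss)
#> Rigid-rotor tumbling time: 4.3 ns
```

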