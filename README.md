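# willisflow

Lumped-parameter (0D) simulation of steady blood flow in the circle of
Willis — the ring of communicating arteries at the base of the brain that
reroutes blood when a feeding vessel is narrowed or congenitally absent.

The package is for people studying cerebral collateral circulation with
reduced-order models: how much total cerebral blood flow is lost when an
internal carotid artery (ICA) stenosis grows, which communicating artery
carries the compensating cross-flow, in which direction, and at what
stenosis degree a communicating artery reverses. It trades the spatial
detail of 3D CFD for a network model that solves in milliseconds, which
makes variant-by-stenosis sweeps and sensitivity studies cheap.

## The model

**Vessels.** Each arterial segment is a cylindrical resistor. For fully
developed laminar tube flow the pressure–flow relation is Poiseuille's law,

    Q = ΔP / R,   R = 128 μ L / (π d⁴),

with segment length `L`, diameter `d`, and an effective dynamic viscosity
`μ` that depends on the flow itself.

**Blood rheology.** Blood is shear-thinning; viscosity follows the Carreau
model

    μ(γ̇) = μ∞ + (μ0 − μ∞) [1 + (λγ̇)²]^((n−1)/2)

with λ = 3.313 s, n = 0.3568, μ0 = 0.056 Pa·s, μ∞ = 0.00345 Pa·s. Each
segment's representative shear rate is the Poiseuille wall shear rate
γ̇ = 32|Q|/(πd³), which couples resistance to flow and makes the network
nonlinear. The solver uses Picard (successive-substitution) iteration with
under-relaxation.

**Boundary conditions.** The inlet pressure is the cerebral perfusion
pressure CPP = MAP − ICP, with the mean arterial pressure estimated from
vital signs by

    MAP ≈ DP + 0.01 · exp(4.14 − 40.74/HR) · (SP − DP).

At the defaults (80/120 mmHg, 80 bpm, ICP 3 mmHg) this gives MAP 95 and
CPP 92 mmHg. Outlets at the ACA/MCA/PCA territories carry constant
pressures (46 / 56 / 43.5 mmHg); the corresponding lumped cerebrovascular
resistances follow from CBF = CPP/CVR at a total cerebral blood flow of
12.5 ml/s split 22/45/33 % over ACA/MCA/PCA.

**Stenosis.** Carotid narrowing is graded by the NASCET definition
S = (1 − dₛ/dₙ) × 100 %, and modelled by splitting the ICA into a healthy
remainder plus a 10 mm stenotic sub-segment of diameter dₙ(1 − S/100);
S = 100 % removes the vessel (occlusion).

**Anatomical variants.** Besides the complete circle, five common
incomplete configurations are built in: absent ACoA, absent right or left
A1, absent right or left PCoA.

## Worked example

```r
library(willisflow)

# boundary conditions from vitals
boundary <- build_boundary_set()
tidy(boundary)
#> # A tibble: 8 x 4
#>   quantity    value units         reported
#>   <chr>       <dbl> <chr>            <dbl>
#> 1 MAP        95.1   mmHg             95
#> 2 CPP_inlet  92.1   mmHg             92
#> 3 outlet_ACA 46     mmHg             46
#> 4 outlet_MCA 56     mmHg             56
#> 5 outlet_PCA 43.5   mmHg             43.5
#> 6 CVR_ACA     0.558 mmHg/(ml/min)     0.56
#> 7 CVR_MCA     0.273 mmHg/(ml/min)     0.27
#> 8 CVR_PCA     0.372 mmHg/(ml/min)     0.37

# calibrate the distal beds so the complete circle carries 12.5 ml/s
# split 22/45/33 over ACA/MCA/PCA, then solve
network <- build_complete_cow() |> calibrate(boundary)
solution <- solve_flows(network, boundary)
glance(solution)
#> # A tibble: 1 x 5
#>   converged iterations total_inflow_ml_s total_efferent_ml_s
#>   <lgl>          <int>             <dbl>               <dbl>
#> 1 TRUE              31              12.5                12.5
#> # i 1 more variable: max_mass_residual_ml_s <dbl>

# all six configurations x stenosis degrees 0/25/50/75/90/100 %
sweep <- run_sweep(network, boundary)
rank_configurations(sweep, degree = 100)
#> # A tibble: 6 x 3
#>    rank variant      total_flow_ml_s
#>   <int> <chr>                  <dbl>
#> 1     1 COMPLETE               11.3
#> 2     2 LPCOA_ABSENT           11.3
#> 3     3 RPCOA_ABSENT           11.2
#> 4     4 RA1_ABSENT             10.9
#> 5     5 ACOA_ABSENT            10.3
#> 6     6 LA1_ABSENT              9.45
```

The ranking says: under right-ICA occlusion, a missing left A1 is the worst
configuration for total cerebral supply (9.45 ml/s of the calibrated
12.5 ml/s baseline), because the left ACA then hangs entirely on cross-flow
through the ACoA from the stenosed side.

Percentage-change reporting against the complete/unstenosed reference, here
applied to the packaged reference flow table (`reference_total_flows()`):

```r
reference_total_flows() |>
  percentage_change_table() |>
  dplyr::filter(degree == 100)
#> # A tibble: 6 x 5
#>   degree variant      total_flow_ml_s pct_change pct_change_reported
#>    <int> <chr>                  <dbl>      <dbl>               <dbl>
#> 1    100 COMPLETE                8.16      -34.8               -34.8
#> 2    100 ACOA_ABSENT             8.07      -35.5               -35.5
#> 3    100 RA1_ABSENT              8.16      -34.8               -34.8
#> 4    100 LA1_ABSENT              7.37      -41.1               -41.1
#> 5    100 RPCOA_ABSENT            8.14      -34.9               -34.9
#> 6    100 LPCOA_ABSENT            8.08      -35.4               -35.4
```

(`pct_change_reported` holds exact two-decimal values — e.g. −34.77 and
−41.09 in the first and fourth rows — shown above at the tibble's default
display precision.)

`reversal_points(sweep)` locates the stenosis degree at which each
communicating artery's flow changes direction (e.g. the right PCoA turns to
feeding the anterior circulation at ~61 % stenosis in the complete circle
on the nominal geometry); `plot_total_flow(sweep)` and
`plot_communicating_flows(sweep)` draw the corresponding line charts.

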