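# metadose

Radionuclide dosimetry for simulated metastatic dissemination.

Radioligand therapy (e.g. PSMA-targeted agents in advanced prostate
cancer) must sterilize not only the lesions a scan can see but the
microscopic disease it cannot. Which radionuclide is best suited for that
depends on how its emitted charged-particle energy is absorbed across the
whole size spectrum of lesions, from single cells to a 50 mm primary.
`metadose` quantifies this with a dynamic disease model: it simulates the
stochastic formation of metastases from a Gompertzian primary, assigns
every simulated lesion a radius-dependent absorbed dose via Monte Carlo
sphere dosimetry, and solves for the activity concentration — and the
corresponding **required absorbed dose** D_req — at which the whole-patient
**metastatic control probability** reaches 99%, for ⁹⁰Y, ¹³¹I, ¹⁷⁷Lu,
¹⁶¹Tb, and ²²⁵Ac.

## The model in brief

* **Growth.** Every tumor follows one Gompertz law
  `V(t) = V0 exp[(SGR0/b)(1 − e^{−bt})]` with `V0 = 1` ng,
  `SGR0 = 7 %/day`, and `b = (SGR0 − SGRd)/ln(Vd/V0)` fixed by
  `SGRd = 0.773 %/day` at a 20 mm tumor — plateauing at ≈65 cm³.
* **Dissemination.** A tumor of volume `V` seeds new single-cell
  metastases at rate `(c/100)(V/1g)^0.67` per day; `c` ranges from 0.16
  (oligometastatic) to 2.56 %/day/g (diffuse). Primary and metastases all
  seed; 7 mm diameter defines detectability.
* **Dosimetry.** Absorbed fractions φ(E, r) of each nuclide's emission
  lines in uniform-activity spheres come from a straight-track
  continuous-slowing-down Monte Carlo over embedded water range–energy
  tables, validated against an independent analytic chord-length oracle.
* **Radiobiology.** Dose at concentration `C_T` (with tumor-to-normal
  ratio TNC = 100 and `T_eff = 51 h`) converts to a biologically effective
  dose `BED = D(1 + D·G/(α/β))`, `G = T_r/(T_r + T_eff)`, and to control
  `TCP = (1 − e^{−α·BED})^h` with `h = 10⁹ cells/cm³ × V` and
  `α = 0.147 Gy⁻¹` calibrated from a 200 Gy BED curing a 50 mm tumor with
  probability 0.99. MCP is the product of TCPs over all of a patient's
  tumors; `D_req` is quoted at full local absorption of the charged
  energy, with ²²⁵Ac's alpha dose weighted ×5 (Gy₅).

See `vignettes/metadose-methods.Rmd` for assumptions, census conventions,
numerical choices, and known limitations.

## Worked example

```r
library(metadose)

tb <- load_radionuclide("161Tb")
lu <- load_radionuclide("177Lu")
grid <- build_phi_grid(list(tb, lu), histories = 20000, seed = 1)

growth <- gompertz_params()
growth
#> <gompertz_params> V0 1e-09 g, SGR0 0.07/d, SGRd 0.00773/d at 4.189 g; b = 0.002811/d, plateau 65.55 g

# one oligometastatic patient, censused at a metastasis-formation event
# once one metastasis is detectable
state <- simulate_patient(growth,
                          dissemination_config(c = 0.16, census = "at_formation"),
                          stop_at_detectable = 1, seed = 11)
state
#> <metastatic_state> census day 1349: 6 metastases (1 detectable), burden 0.216 cm3; primary 37.4 cm3

solve_dreq(state, tb, grid)
#> <dreq_result> 161Tb: C_T = 2.647e+07 Bq/g, D_req = 224.4 Gy (MCP 0.9900, 27 iterations)
solve_dreq(state, lu, grid)
#> <dreq_result> 177Lu: C_T = 8.184e+07 Bq/g, D_req = 506.4 Gy (MCP 0.9900, 27 iterations)
```

For this patient — a 37 cm³ primary, one visible metastasis, and five
occult ones down to a freshly shed single cell — a ¹⁶¹Tb concentration of
2.6·10⁷ Bq/g controls everything with 99% probability, corresponding to a
required dose of 224 Gy; ¹⁷⁷Lu needs 506 Gy because far less of its
electron energy is absorbed in the microscopic lesions. Cohort-level
summaries of the disease model itself:

```r
summarize_cohort(simulate_cohort(300, growth,
                                 dissemination_config(c = 2.56), 20, seed = 42))
#>      c n_detectable replicates formation_time_d formation_time_median_d
#> 1 2.56           20        300             1420                    1417
#>   median_size_cm3 size_p2.5_cm3 size_p97.5_cm3 n_metastases burden_cm3
#> 1           0.865         0.184           9.72          223       38.1
```

i.e. in the diffuse scenario the twentieth metastasis becomes visible
around day 1420, the typical visible lesion is below 1 cm³, and 223
metastases of all sizes carry ≈38 cm³ of disease. `dreq_table()` sweeps
nuclides, milestones, and both dissemination patterns into the summary
table of required doses, and `inst/cli/metadose` exposes `simulate`,
`dreq`, and `phi` as shell commands.

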