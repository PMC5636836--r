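# ectopred

Bioenergetics estimation of predation rates by ectothermic marine apex
predators.

Direct measurement of predation rates by large marine predators is rarely
possible, yet those rates are exactly what ecosystem models and fisheries
stock assessments need: predation is often the dominant component of
natural mortality for exploited species. When the predator's demographics,
diet and local abundance are known, a bioenergetics model offers a
practical alternative: compute how much energy the predator population must
spend over a residency season, decide what fraction of that budget each
prey species supplies, and divide by the energy one prey individual is
worth. `ectopred` implements that pipeline for a seasonal aggregation of an
ectothermic shark preying on elasmobranchs, teleosts, cephalopods and
marine mammals, with Monte Carlo propagation of parameter uncertainty. It
was built around the well-studied case of broadnose sevengill sharks
(*Notorynchus cepedianus*) feeding on gummy sharks (*Mustelus antarcticus*)
and other prey in a temperate Australian embayment, and every default
parameter reproduces that system.

## The model

Routine metabolic rate of an individual of body mass *M* (kg) follows an
allometric power law for free-swimming ectothermic sharks, referenced to
20 °C:

    MR = 214 · M^0.79        [mg O2 h⁻¹]

Rates are corrected to ambient water temperature *T* with a Q10 factor
(point value 2.2; uniform 1.3–3.0 in uncertainty mode),

    MR(T) = MR · Q10^((T − 20)/10),

converted to energy with 68.3 mg O2 kJ⁻¹ (respiratory exchange ratio
0.88), and increased 5% for the cost of growth, plus a further 5% for the
cost of reproduction in one third of mature females. Summing daily
expenditure over three 84-day seasons (spring/summer/autumn at
14.0/19.1/16.9 °C), averaging over a representative sample of individuals,
and scaling by population size *N* gives the population energy budget over
the 36-week (6048 h) residency. The number of individuals of prey species
*x* consumed is then

    P_x = MR_pop · F_x / E_x,

where `F_x` is the fraction of the diet supplied by species *x* — estimated
from stomach-content records under three standard indices (frequency of
occurrence; percent partly-digested weight; count × average weight) — and
`E_x = energy density · body mass · 0.73` is the assimilable energy of one
prey individual. Uncertainty in abundance (log-normal), diet composition
(stomach-level bootstrap), Q10, temperature, body mass and the allometric
parameters is propagated over 1000 Monte Carlo draws per scenario.

## Worked example

```r
library(ectopred)

# a seeded synthetic predator sample at the study demographics:
# 294 sharks, mass 42 +/- 22 kg truncated to 2.8-88 kg, 216 females
pred <- generate_predators(sampling_config(seed = 1))

round(population_mean_daily_mr(pred, 16.7))
#> [1] 1109

res <- run_scenario(
  scenario_config(diet_variant = 1,
                  abundance = abundance_scenario("N2"),  # 1130 +/- 137
                  n_sims = 1000, seed = 1),
  pred)
res
#> Scenario: diet variant 1, abundance N2 (1130 +/- 137), 1000 draws
#>      species mean_count ci_low ci_high biomass_t
#>  gummy_shark       9654   7593   12135      17.4
```

The first number is the mean cost-adjusted daily energy expenditure
(kJ d⁻¹) of one shark at the overall mean water temperature of 16.7 °C.
The scenario result says that a population of ~1130 sevengill sharks,
attributing 25% of its energy budget to gummy sharks (the reported
frequency of occurrence), consumes on the order of 9,700 gummy sharks —
about 17 tonnes — over the 36-week season; the interval is the 2.5th–97.5th
percentile of the Monte Carlo draws, dominated by abundance uncertainty.

Sensitivity of the estimate to the temperature coefficient (colder-blooded
physiology means a smaller down-correction from the 20 °C reference, hence
more prey consumed at 16.7 °C):

```r
sensitivity_sweep(scenario_config(1, abundance_scenario("N2"),
                                  n_sims = 500, seed = 1),
                  pred, axis = "q10", grid = c(1.3, 2.2, 3.0))
#>   axis value mean_count
#> 1  q10   1.3  11369.080
#> 2  q10   2.2   9654.536
#> 3  q10   3.0   8815.198
```

`cmd_generate()`, `cmd_simulate()` and `cmd_sensitivity()` run the whole
pipeline (six scenarios: three diet variants × two abundance scenarios)
and write CSV tables plus a manifest from which any run can be reproduced
byte-for-byte (`rerun_from_manifest()`). A thin CLI wrapper ships in
`inst/cli/ectopred`.

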