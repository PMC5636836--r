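#' Metabolic parameter set
#'
#' Parameters of the routine-metabolism model: an allometric power law in
#' body mass giving oxygen consumption at a reference temperature, a Q10
#' temperature coefficient, an oxycalorific conversion, and proportional
#' surcharges for the costs of growth and reproduction over the 36-week
#' (252-day) seasonal residency.
#'
#' @param allometric_coeff mg O2 h^-1 kg^-b at the reference temperature
#'   (default 214, pooled free-swimming ectothermic sharks).
#' @param allometric_exp Mass exponent b (default 0.79).
#' @param ref_temp_c Reference temperature of the power law, degrees C
#'   (default 20).
#' @param q10 Q10 temperature coefficient point value (default 2.2).
#' @param q10_range Range used when Q10 is treated as uncertain (uniform,
#'   default 1.3-3.0, spanning published elasmobranch values).
#' @param oxycal mg O2 per kJ (default 68.3, at respiratory exchange
#'   ratio 0.88).
#' @param growth_surcharge Proportional increase in expenditure for the cost
#'   of growth, applied to every individual (default 0.05).
#' @param repro_surcharge Proportional increase for the cost of reproduction
#'   (default 0.05), applied only to reproductively active mature females.
#' @param repro_female_fraction Fraction of mature females reproductively
#'   active in a given year (default 1/3, a three-year cycle).
#' @param days_per_period Days in the modelled residency period (default 252
#'   = 36 weeks; 6048 h).
#' @return List of class \code{"metabolic_params"}.
#' @export
metabolic_params <- function(allometric_coeff = 214, allometric_exp = 0.79,
                             ref_temp_c = 20, q10 = 2.2,
                             q10_range = c(1.3, 3.0), oxycal = 68.3,
                             growth_surcharge = 0.05, repro_surcharge = 0.05,
                             repro_female_fraction = 1 / 3,
                             days_per_period = 252) {
  stopifnot(allometric_coeff > 0,
            allometric_exp > 0, allometric_exp < 1.5,
            q10 > 0, length(q10_range) == 2, q10_range[1] <= q10_range[2],
            q10_range[1] >= 1,
            oxycal > 0, growth_surcharge >= 0, repro_surcharge >= 0,
            repro_female_fraction >= 0, repro_female_fraction <= 1,
            days_per_period > 0)
  structure(list(allometric_coeff = allometric_coeff,
                 allometric_exp = allometric_exp,
                 ref_temp_c = ref_temp_c, q10 = q10, q10_range = q10_range,
                 oxycal = oxycal, growth_surcharge = growth_surcharge,
                 repro_surcharge = repro_surcharge,
                 repro_female_fraction = repro_female_fraction,
                 days_per_period = days_per_period,
                 hours_per_period = 24 * days_per_period),
            class = "metabolic_params")
}

#' Seasonal temperature regime
#'
#' Mean water temperatures per season and the number of days each season
#' contributes to the residency period. Defaults are the three-season
#' (spring/summer/autumn) regime of the study system: 14.0, 19.1 and
#' 16.9 degrees C over three equal 84-day seasons (overall mean 16.7).
#'
#' @param season_temps_c Named numeric vector of seasonal mean temperatures.
#' @param season_days Days per season; must sum to the modelled period.
#' @return List of class \code{"temperature_regime"} with the day-weighted
#'   \code{overall_mean_c}.
#' @export
temperature_regime <- function(season_temps_c = c(spring = 14.0,
                                                  summer = 19.1,
                                                  autumn = 16.9),
                               season_days = rep(84, length(season_temps_c))) {
  stopifnot(length(season_temps_c) == length(season_days),
            all(season_days > 0))
  structure(list(season_temps_c = season_temps_c,
                 season_days = season_days,
                 overall_mean_c = sum(season_temps_c * season_days) /
                   sum(season_days)),
            class = "temperature_regime")
}

#' Routine metabolic rate at the reference temperature
#'
#' Allometric power law \eqn{MR = a M^b} in mg O2 per hour, valid at the
#' parameter set's reference temperature.
#'
#' @param mass_kg Body mass in kg (vectorized, all positive).
#' @param params A [metabolic_params()] object.
#' @return mg O2 per hour.
#' @export
#' @examples
#' routine_mr(42)  # ~4100 mg O2/h
routine_mr <- function(mass_kg, params = metabolic_params()) {
  stopifnot(inherits(params, "metabolic_params"))
  if (any(!is.finite(mass_kg)) || any(mass_kg <= 0)) {
    stop("body mass must be positive")
  }
  params$allometric_coeff * mass_kg^params$allometric_exp
}

#' Q10 temperature correction
#'
#' Scales a physiological rate from the reference temperature to an ambient
#' temperature: \eqn{rate \cdot Q_{10}^{(T - T_{ref})/10}}.
#'
#' @param rate Non-negative rate (any units); vectorized.
#' @param temp_c Ambient temperature, degrees C.
#' @param params A [metabolic_params()] object.
#' @param q10 Q10 value; defaults to the point value in \code{params}.
#' @return Rate at \code{temp_c}, same units.
#' @export
q10_adjust <- function(rate, temp_c, params = metabolic_params(),
                       q10 = params$q10) {
  stopifnot(inherits(params, "metabolic_params"), all(rate >= 0))
  if (any(q10 <= 0)) stop("q10 must be positive")
  rate * q10^((temp_c - params$ref_temp_c) / 10)
}

#' Convert oxygen consumption to daily energy expenditure
#'
#' mg O2 per hour to kJ per day via the oxycalorific coefficient.
#'
#' @inheritParams q10_adjust
#' @param rate_mgo2_h Oxygen consumption rate, mg O2 per hour.
#' @return kJ per day.
#' @export
#' @examples
#' mgo2_to_kj_per_day(4100)  # ~1441 kJ/d
mgo2_to_kj_per_day <- function(rate_mgo2_h, params = metabolic_params()) {
  stopifnot(inherits(params, "metabolic_params"), all(rate_mgo2_h >= 0))
  rate_mgo2_h * 24 / params$oxycal
}

#' Apply growth and reproduction cost surcharges
#'
#' Every individual pays the growth surcharge; the reproduction surcharge is
#' paid only by individuals flagged as reproductively active, which must be
#' mature females.
#'
#' @param rate Energy expenditure rate (any units); vectorized.
#' @param sex Character vector, \code{"F"} or \code{"M"}.
#' @param mature Logical vector.
#' @param repro_selected Logical vector: reproduction surcharge applies.
#' @param params A [metabolic_params()] object.
#' @return Cost-adjusted rate.
#' @export
apply_costs <- function(rate, sex, mature, repro_selected = FALSE,
                        params = metabolic_params()) {
  stopifnot(inherits(params, "metabolic_params"), all(rate >= 0))
  n <- max(length(rate), length(sex), length(mature), length(repro_selected))
  sex <- rep_len(sex, n); mature <- rep_len(mature, n)
  repro_selected <- rep_len(repro_selected, n)
  if (any(repro_selected & !(sex == "F" & mature))) {
    stop("reproduction surcharge selected for a male or immature female")
  }
  rate * (1 + params$growth_surcharge) *
    ifelse(repro_selected, 1 + params$repro_surcharge, 1)
}

#' Select the reproductively active subset of mature females
#'
#' Under the individual-assignment interpretation, exactly
#' \code{ceiling(n_mature_females * repro_female_fraction)} mature females
#' carry the reproduction surcharge; the subset is a seeded random draw so
#' results are reproducible.
#'
#' @param predators Predator data frame (\code{sex}, \code{mature}).
#' @param params A [metabolic_params()] object.
#' @param seed Integer seed for the subset draw.
#' @return Logical vector over rows of \code{predators}.
#' @export
select_repro_females <- function(predators, params = metabolic_params(),
                                 seed = 1) {
  mf <- which(predators$sex == "F" & predators$mature)
  sel <- rep(FALSE, nrow(predators))
  k <- ceiling(length(mf) * params$repro_female_fraction)
  if (k > 0) {
    chosen <- with_preserved_rng({
      set.seed(as.integer(seed))
      sample(mf, k)
    })
    sel[chosen] <- TRUE
  }
  sel
}

# per-individual cost-adjusted daily expenditure (kJ/d) at one temperature
daily_expenditure <- function(mass_kg, sex, mature, repro_selected, temp_c,
                              params, q10 = params$q10) {
  apply_costs(q10_adjust(mgo2_to_kj_per_day(routine_mr(mass_kg, params),
                                            params),
                         temp_c, params, q10 = q10),
              sex, mature, repro_selected, params)
}

#' Energy expenditure of one individual over the residency period
#'
#' Sums the cost-adjusted, temperature-corrected daily expenditure over the
#' seasons of the regime: for each season, the daily rate at that season's
#' mean temperature times the number of days.
#'
#' @param predators Data frame with \code{mass_kg}, \code{sex},
#'   \code{mature} (one or more rows).
#' @param regime A [temperature_regime()] object.
#' @param params A [metabolic_params()] object.
#' @param repro_selected Logical vector (default no reproduction surcharge).
#' @param q10 Q10 value; defaults to the point value in \code{params}.
#' @return kJ per period, one value per predator row.
#' @export
individual_period_energy <- function(predators, regime = temperature_regime(),
                                     params = metabolic_params(),
                                     repro_selected = FALSE,
                                     q10 = params$q10) {
  stopifnot(inherits(regime, "temperature_regime"))
  if (abs(sum(regime$season_days) - params$days_per_period) > 1e-9) {
    stop("season days must sum to the modelled period (",
         params$days_per_period, " d)")
  }
  temps <- unname(regime$season_temps_c)
  days <- unname(regime$season_days)
  e <- 0
  for (s in seq_along(temps)) {
    e <- e + daily_expenditure(predators$mass_kg, predators$sex,
                               predators$mature, repro_selected,
                               temps[s], params, q10) * days[s]
  }
  e
}

#' Population mean daily routine expenditure at one temperature
#'
#' Averages the cost-adjusted daily expenditure over a sample of individuals
#' at a single water temperature. The reproduction surcharge is carried
#' either by a seeded random subset of mature females (\code{"subset"}, the
#' default: each selected female pays the full surcharge) or fractionally by
#' all mature females (\code{"fractional"}: every mature female pays
#' \code{repro_female_fraction} of the surcharge in expectation).
#'
#' @param predators Predator data frame (\code{mass_kg}, \code{sex},
#'   \code{mature}), non-empty.
#' @param temp_c Water temperature, degrees C.
#' @param params A [metabolic_params()] object.
#' @param repro \code{"subset"} or \code{"fractional"}.
#' @param seed Seed for the subset draw.
#' @param q10 Q10 value; defaults to the point value in \code{params}.
#' @return Mean kJ per day.
#' @export
population_mean_daily_mr <- function(predators, temp_c,
                                     params = metabolic_params(),
                                     repro = c("subset", "fractional"),
                                     seed = 1, q10 = params$q10) {
  if (NROW(predators) == 0) stop("empty predator sample")
  repro <- match.arg(repro)
  base <- q10_adjust(mgo2_to_kj_per_day(routine_mr(predators$mass_kg, params),
                                        params),
                     temp_c, params, q10 = q10)
  if (repro == "subset") {
    sel <- select_repro_females(predators, params, seed)
    mean(apply_costs(base, predators$sex, predators$mature, sel, params))
  } else {
    mf <- predators$sex == "F" & predators$mature
    fac <- (1 + params$growth_surcharge) *
      ifelse(mf, 1 + params$repro_surcharge * params$repro_female_fraction, 1)
    mean(base * fac)
  }
}

#' Routine energy expenditure of the whole population over the period
#'
#' The sample of individuals is taken as representative of population
#' demographics at any given time; the mean individual period energy is
#' scaled by the population size.
#'
#' @inheritParams individual_period_energy
#' @param n_population Number of predators in the population (> 0).
#' @param repro,seed As in [population_mean_daily_mr()].
#' @return kJ per period for the whole population.
#' @export
population_period_energy <- function(predators, regime = temperature_regime(),
                                     params = metabolic_params(),
                                     n_population,
                                     repro = c("subset", "fractional"),
                                     seed = 1, q10 = params$q10) {
  stopifnot(n_population > 0)
  if (NROW(predators) == 0) stop("empty predator sample")
  repro <- match.arg(repro)
  if (repro == "subset") {
    sel <- select_repro_females(predators, params, seed)
    mean(individual_period_energy(predators, regime, params, sel, q10)) *
      n_population
  } else {
    base <- individual_period_energy(predators, regime, params, FALSE, q10)
    mf <- predators$sex == "F" & predators$mature
    fac <- ifelse(mf, 1 + params$repro_surcharge * params$repro_female_fraction,
                  1)
    mean(base * fac) * n_population
  }
}
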