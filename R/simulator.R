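#' Predator abundance scenario
#'
#' Population size of the predator in the bay over the residency period,
#' modelled as a log-normal on the natural scale (parameters by moment
#' matching). The two mark-recapture-based defaults are \code{"N1"}
#' (562 +/- 71 sharks) and \code{"N2"} (1130 +/- 137 sharks).
#'
#' @param label \code{"N1"}, \code{"N2"}, or any label when \code{mean} is
#'   supplied.
#' @param mean,sd Mean and SD of population size (sharks); defaults follow
#'   the label.
#' @return List of class \code{"abundance_scenario"}.
#' @export
abundance_scenario <- function(label = c("N2", "N1"), mean = NULL, sd = NULL) {
  if (is.null(mean)) {
    label <- match.arg(label)
    mean <- switch(label, N1 = 562, N2 = 1130)
    sd <- switch(label, N1 = 71, N2 = 137)
  } else {
    label <- as.character(label[1])
    if (is.null(sd)) sd <- 0
  }
  stopifnot(mean > 0, sd >= 0)
  structure(list(label = label, mean = mean, sd = sd),
            class = "abundance_scenario")
}

#' Scenario configuration
#'
#' One model run: a diet-composition variant crossed with an abundance
#' scenario, under a temperature regime and metabolic parameter set, with
#' switches controlling which parameters are resampled per Monte Carlo draw.
#' Default runs resample predator abundance and (for variants 2-3) diet
#' composition, holding Q10 at its point value and temperatures at their
#' seasonal means; the wider-uncertainty mode (Q10 uniform over its range,
#' temperature jitter, body-mass and allometric resampling) is enabled
#' through \code{uncertainty}.
#'
#' @param diet_variant 1 (frequency of occurrence, focal species only),
#'   2 (percent weight) or 3 (count x average weight).
#' @param abundance An [abundance_scenario()].
#' @param regime A [temperature_regime()].
#' @param metabolic A [metabolic_params()].
#' @param n_sims Monte Carlo draws (default 1000).
#' @param uncertainty Named logical list: \code{abundance},
#'   \code{prey_composition}, \code{q10}, \code{temperature},
#'   \code{body_mass}, \code{allometric}.
#' @param focal_species Species reported under variant 1 (and by
#'   sensitivity sweeps).
#' @param focal_fraction Diet fraction of the focal species under variant 1
#'   (default 0.25, the reported frequency of occurrence); set \code{NULL}
#'   to estimate it from the stomach records instead.
#' @param temp_sd SD of per-draw seasonal temperature jitter, degrees C
#'   (used when \code{uncertainty$temperature}).
#' @param allometric_cv Coefficients of variation for per-draw log-normal
#'   resampling of the allometric coefficient and exponent (no SDs are
#'   reported for these; defaults 0).
#' @param repro \code{"subset"} or \code{"fractional"} reproduction-cost
#'   assignment (see [population_mean_daily_mr()]).
#' @param seed Integer seed; all scenario randomness derives from it.
#' @return List of class \code{"scenario_config"}.
#' @export
scenario_config <- function(diet_variant = 1,
                            abundance = abundance_scenario("N2"),
                            regime = temperature_regime(),
                            metabolic = metabolic_params(),
                            n_sims = 1000,
                            uncertainty = list(),
                            focal_species = "gummy_shark",
                            focal_fraction = 0.25,
                            temp_sd = 0.5,
                            allometric_cv = c(coef = 0, exp = 0),
                            repro = c("subset", "fractional"),
                            seed = 1) {
  stopifnot(diet_variant %in% 1:3, inherits(abundance, "abundance_scenario"),
            inherits(regime, "temperature_regime"),
            inherits(metabolic, "metabolic_params"), n_sims >= 1,
            temp_sd >= 0, all(allometric_cv >= 0))
  un <- list(abundance = TRUE, prey_composition = TRUE, q10 = FALSE,
             temperature = FALSE, body_mass = FALSE, allometric = FALSE)
  bad <- setdiff(names(uncertainty), names(un))
  if (length(bad)) stop("unknown uncertainty switch: ",
                        paste(bad, collapse = ", "))
  un[names(uncertainty)] <- uncertainty
  if (!is.null(focal_fraction)) {
    stopifnot(focal_fraction >= 0, focal_fraction <= 1)
  }
  repro <- match.arg(repro)
  structure(list(diet_variant = as.integer(diet_variant),
                 abundance = abundance, regime = regime,
                 metabolic = metabolic, n_sims = as.integer(n_sims),
                 uncertainty = un, focal_species = focal_species,
                 focal_fraction = focal_fraction, temp_sd = temp_sd,
                 allometric_cv = allometric_cv, repro = repro,
                 seed = seed),
            class = "scenario_config")
}

#' Number of prey individuals consumed over the period
#'
#' The core predation identity \eqn{P_x = MR \cdot F_x / E_x}: the energy
#' budget attributed to species \eqn{x} divided by the assimilable energy of
#' one individual. Real-valued; rounding happens only in rendered tables.
#'
#' @param total_energy_kj Population energy expenditure over the period, kJ.
#' @param fraction Diet fraction \eqn{F_x} in [0, 1].
#' @param prey_energy_kj Assimilable energy per prey individual, kJ (> 0).
#' @return Individuals consumed per period (vectorized).
#' @export
#' @examples
#' predation_count(3.3e8, 0.25, 8247)
predation_count <- function(total_energy_kj, fraction, prey_energy_kj) {
  stopifnot(all(total_energy_kj >= 0),
            all(fraction >= 0), all(fraction <= 1))
  if (any(prey_energy_kj <= 0)) stop("prey energy must be positive")
  total_energy_kj * fraction / prey_energy_kj
}

# per-draw diet fractions for the configured variant
draw_fractions <- function(cfg, stomachs, profiles) {
  switch(cfg$diet_variant,
         frequency_of_occurrence(stomachs),
         percent_weight(stomachs),
         count_avg_weight(stomachs, profiles))
}

#' Run one Monte Carlo scenario
#'
#' For each draw: sample population size from the abundance scenario's
#' log-normal; resample whichever uncertain parameters are enabled (Q10
#' uniform over its range, seasonal temperatures with normal jitter,
#' predator body masses by bootstrap, allometric parameters log-normally by
#' CV, diet composition by a stomach-level bootstrap); recompute the
#' population's period energy budget and per-species diet fractions; and
#' convert to per-species consumption counts via [predation_count()].
#' Results are summarized as the mean and the 2.5th-97.5th percentile
#' interval of the draws. A fixed seed reproduces the draw matrix exactly.
#'
#' @param cfg A [scenario_config()].
#' @param predators Predator sample data frame (\code{mass_kg}, \code{sex},
#'   \code{mature}).
#' @param stomachs Stomach records (required for variants 2-3, or for
#'   variant 1 with \code{focal_fraction = NULL}).
#' @param profiles A [prey_profiles()] table. Profiles whose length-weight
#'   conversion fails [validate_profiles()] are rejected unless
#'   \code{allow_flagged}.
#' @param allow_flagged Keep profiles flagged by validation (default
#'   \code{FALSE}).
#' @return List of class \code{"scenario_result"}: \code{draws} (matrix,
#'   draws x species), \code{summary} (species, mean_count, ci_low, ci_high,
#'   biomass_t), \code{sampled} (per-draw abundance and Q10), and the
#'   configuration.
#' @export
run_scenario <- function(cfg, predators, stomachs = NULL,
                         profiles = prey_profiles(), allow_flagged = FALSE) {
  stopifnot(inherits(cfg, "scenario_config"), NROW(predators) > 0)
  val <- validate_profiles(profiles)
  if (!allow_flagged && any(val$status == "flag")) {
    stop("profiles failed length-weight validation: ",
         paste(val$species[val$status == "flag"], collapse = ", "),
         " (see validate_profiles(); use allow_flagged = TRUE to override)")
  }
  un <- cfg$uncertainty
  n_sims <- cfg$n_sims
  params <- cfg$metabolic
  seeds <- derive_seeds(cfg$seed, c("repro", "abundance", "q10",
                                    "temperature", "mass", "allometric",
                                    "bootstrap"))

  variant1_fixed <- cfg$diet_variant == 1 && !is.null(cfg$focal_fraction)
  if (!variant1_fixed && is.null(stomachs)) {
    stop("stomach records are required to estimate diet fractions")
  }
  if (variant1_fixed) {
    base_fr <- stats::setNames(cfg$focal_fraction, cfg$focal_species)
  } else {
    base_dc <- draw_fractions(cfg, stomachs, profiles)
    base_fr <- base_dc$fractions
    if (cfg$diet_variant == 1) {
      base_fr <- base_fr[cfg$focal_species]
      if (anyNA(base_fr)) stop("focal species absent from stomach records")
    }
  }
  species <- names(base_fr)
  e_prey <- vapply(species, function(s) available_energy(profiles, s),
                   numeric(1))

  # per-draw sampled parameters, one substream each
  abn <- with_preserved_rng({
    set.seed(seeds[["abundance"]])
    if (un$abundance && cfg$abundance$sd > 0) {
      p <- lnorm_moment_params(cfg$abundance$mean, cfg$abundance$sd)
      rlnorm(n_sims, p["meanlog"], p["sdlog"])
    } else rep(cfg$abundance$mean, n_sims)
  })
  q10s <- with_preserved_rng({
    set.seed(seeds[["q10"]])
    if (un$q10) runif(n_sims, params$q10_range[1], params$q10_range[2])
    else rep(params$q10, n_sims)
  })
  n_seas <- length(cfg$regime$season_temps_c)
  temps <- with_preserved_rng({
    set.seed(seeds[["temperature"]])
    base <- matrix(cfg$regime$season_temps_c, n_sims, n_seas, byrow = TRUE)
    if (un$temperature && cfg$temp_sd > 0) {
      base + matrix(rnorm(n_sims * n_seas, 0, cfg$temp_sd), n_sims, n_seas)
    } else base
  })
  mass_idx <- with_preserved_rng({
    set.seed(seeds[["mass"]])
    if (un$body_mass) {
      matrix(sample.int(nrow(predators), n_sims * nrow(predators),
                        replace = TRUE), n_sims)
    } else NULL
  })
  allo <- with_preserved_rng({
    set.seed(seeds[["allometric"]])
    cv <- cfg$allometric_cv
    draw1 <- function(m, cv) {
      if (un$allometric && cv > 0) {
        p <- lnorm_moment_params(m, m * cv)
        rlnorm(n_sims, p["meanlog"], p["sdlog"])
      } else rep(m, n_sims)
    }
    list(coef = draw1(params$allometric_coeff, cv[["coef"]]),
         exp = draw1(params$allometric_exp, cv[["exp"]]))
  })

  repro_sel <- select_repro_females(predators, params, seeds[["repro"]])

  # mean individual period energy per draw; constant unless a metabolic
  # input is resampled
  need_loop <- un$q10 || un$temperature || un$body_mass || un$allometric
  mean_ind_energy <- function(pred, q10, temps_d, coef, expn) {
    p <- params
    p$allometric_coeff <- coef
    p$allometric_exp <- expn
    reg <- cfg$regime
    reg$season_temps_c <- temps_d
    if (cfg$repro == "subset") {
      sel <- if (identical(pred, predators)) repro_sel else
        select_repro_females(pred, p, seeds[["repro"]])
      mean(individual_period_energy(pred, reg, p, sel, q10))
    } else {
      base <- individual_period_energy(pred, reg, p, FALSE, q10)
      mf <- pred$sex == "F" & pred$mature
      mean(base * ifelse(mf, 1 + p$repro_surcharge * p$repro_female_fraction,
                         1))
    }
  }
  if (!need_loop) {
    e_ind <- rep(mean_ind_energy(predators, params$q10,
                                 cfg$regime$season_temps_c,
                                 params$allometric_coeff,
                                 params$allometric_exp), n_sims)
  } else {
    e_ind <- vapply(seq_len(n_sims), function(d) {
      pred <- if (is.null(mass_idx)) predators else
        predators[mass_idx[d, ], , drop = FALSE]
      mean_ind_energy(pred, q10s[d], temps[d, ], allo$coef[d], allo$exp[d])
    }, numeric(1))
  }
  e_pop <- e_ind * abn

  # per-draw fractions
  boot <- un$prey_composition && !variant1_fixed
  fr_mat <- matrix(0, n_sims, length(species),
                   dimnames = list(NULL, species))
  if (boot) {
    with_preserved_rng({
      set.seed(seeds[["bootstrap"]])
      for (d in seq_len(n_sims)) {
        bs <- bootstrap_stomachs(stomachs)
        fr <- draw_fractions(cfg, bs, profiles)$fractions
        if (cfg$diet_variant == 1) fr <- fr[cfg$focal_species]
        fr_mat[d, names(fr)[!is.na(fr)]] <- fr[!is.na(fr)]
      }
    })
  } else {
    fr_mat <- matrix(base_fr, n_sims, length(species), byrow = TRUE,
                     dimnames = list(NULL, species))
  }

  draws <- sweep(fr_mat, 1, e_pop, "*")
  draws <- sweep(draws, 2, e_prey, "/")

  mm <- profiles$mean_mass_kg[match(species, profiles$species)]
  summ <- data.frame(
    species = species,
    mean_count = colMeans(draws),
    ci_low = apply(draws, 2, stats::quantile, 0.025, names = FALSE),
    ci_high = apply(draws, 2, stats::quantile, 0.975, names = FALSE),
    biomass_t = colMeans(draws) * mm / 1000,
    row.names = NULL)
  structure(list(draws = draws, summary = summ,
                 sampled = data.frame(abundance = abn, q10 = q10s),
                 e_pop = e_pop, prey_energy_kj = e_prey, config = cfg),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cfg <- x$config
  cat("Scenario: diet variant ", cfg$diet_variant, ", abundance ",
      cfg$abundance$label, " (", cfg$abundance$mean, " +/- ",
      cfg$abundance$sd, "), ", cfg$n_sims, " draws\n", sep = "")
  s <- x$summary
  s$mean_count <- round(s$mean_count)
  s$ci_low <- round(s$ci_low)
  s$ci_high <- round(s$ci_high)
  s$biomass_t <- round(s$biomass_t, 1)
  print.data.frame(s, row.names = FALSE)
  invisible(x)
}

#' Biomass of prey consumed
#'
#' Mean consumption counts converted to tonnes per species via the profile
#' mean body masses.
#'
#' @param result A [run_scenario()] result.
#' @param profiles A [prey_profiles()] table.
#' @return Named numeric vector, tonnes per species.
#' @export
biomass_consumed <- function(result, profiles = prey_profiles()) {
  stopifnot(inherits(result, "scenario_result"))
  mm <- profiles$mean_mass_kg[match(result$summary$species,
                                    profiles$species)]
  if (anyNA(mm)) stop("species without a mean mass in profiles")
  stats::setNames(result$summary$mean_count * mm / 1000,
                  result$summary$species)
}

#' One-parameter sensitivity sweep
#'
#' Re-runs a scenario with one parameter fixed at each grid value (all
#' others at their configured values, matched seeds across grid points) and
#' reports the focal species' mean consumption count. Axes:
#' \code{"temperature"} (a flat regime at the grid temperature),
#' \code{"q10"}, and \code{"abundance"} (scenario mean, SD scaled to keep
#' the CV).
#'
#' @inheritParams run_scenario
#' @param axis \code{"temperature"}, \code{"q10"} or \code{"abundance"}.
#' @param grid Numeric vector of parameter values (non-empty).
#' @return Data frame (\code{axis}, \code{value}, \code{mean_count}).
#' @export
sensitivity_sweep <- function(cfg, predators, stomachs = NULL,
                              profiles = prey_profiles(),
                              axis = c("temperature", "q10", "abundance"),
                              grid) {
  axis <- match.arg(axis)
  stopifnot(length(grid) >= 1, is.numeric(grid))
  mean_focal <- function(cfg_i) {
    res <- run_scenario(cfg_i, predators, stomachs, profiles)
    s <- res$summary
    i <- match(cfg$focal_species, s$species)
    if (is.na(i)) stop("focal species not in scenario output")
    s$mean_count[i]
  }
  vals <- vapply(grid, function(v) {
    cfg_i <- cfg
    if (axis == "temperature") {
      cfg_i$regime$season_temps_c[] <- v
      cfg_i$uncertainty$temperature <- FALSE
    } else if (axis == "q10") {
      cfg_i$metabolic$q10 <- v
      cfg_i$uncertainty$q10 <- FALSE
    } else {
      scale <- v / cfg$abundance$mean
      cfg_i$abundance$mean <- v
      cfg_i$abundance$sd <- cfg$abundance$sd * scale
    }
    mean_focal(cfg_i)
  }, numeric(1))
  data.frame(axis = axis, value = grid, mean_count = vals)
}

#' Maximum-likelihood log-normal fit to consumption draws
#'
#' Fits a log-normal to a vector of positive counts by maximum likelihood
#' (mean and ML standard deviation of the log counts) and returns a density
#' grid for plotting the fitted predation-probability curve.
#'
#' @param counts Positive numeric vector, length >= 10.
#' @param n_grid Number of density grid points.
#' @return List of class \code{"lognormal_fit"}: \code{meanlog},
#'   \code{sdlog}, and a data frame \code{density} (\code{x}, \code{d}).
#' @export
fit_lognormal <- function(counts, n_grid = 200) {
  if (length(counts) < 10) stop("need at least 10 counts")
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stop("counts must be positive")
  }
  lx <- log(counts)
  meanlog <- mean(lx)
  sdlog <- sqrt(mean((lx - meanlog)^2))  # ML denominator n
  lo <- min(counts)
  hi <- max(counts)
  if (sdlog > 0) {
    lo <- qlnorm(0.001, meanlog, sdlog)
    hi <- qlnorm(0.999, meanlog, sdlog)
  }
  x <- seq(lo, hi, length.out = n_grid)
  structure(list(meanlog = meanlog, sdlog = sdlog,
                 density = data.frame(x = x,
                                      d = if (sdlog > 0)
                                        dlnorm(x, meanlog, sdlog)
                                      else as.numeric(x == exp(meanlog)))),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat("Log-normal fit: meanlog", format(x$meanlog, digits = 6),
      " sdlog", format(x$sdlog, digits = 6),
      " (median", format(exp(x$meanlog), digits = 6), ")\n")
  invisible(x)
}
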