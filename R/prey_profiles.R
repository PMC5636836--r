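#' Prey (and predator) profiles: sizes, length-weight conversions, energy
#'
#' The packaged profile table describes each prey species or group consumed
#' by the predator, plus the predator itself: length statistics (total length
#' for sharks and chimaeras, disc width for batoids), sex-specific
#' length-weight conversions, body-mass statistics, and wet-tissue energy
#' density (kcal per g). Conversions come in two forms:
#' \itemize{
#'   \item power: \eqn{M = c \cdot e \cdot (L \cdot s)^{b}} with length scale
#'     \eqn{s} (10 where the regression was fitted on lengths in mm);
#'   \item quadratic: \eqn{M = a L^2 + b L + c} with \eqn{L} in cm.
#' }
#' Two published coefficients are dimensionally inconsistent as printed (the
#' female gummy/school-shark power coefficient, off by twenty orders of
#' magnitude, and the dogshark formula, whose literal value predicts
#' kilotonne dogfish); the packaged table carries corrected values that
#' reproduce the reported mean masses, and retains the printed ones so that
#' [validate_profiles()] can demonstrate the inconsistency (load them with
#' \code{corrected = FALSE}).
#'
#' @param file Path to a profile CSV in the packaged schema; default uses the
#'   table shipped with the package.
#' @param corrected Logical; if \code{FALSE}, substitute the literal printed
#'   coefficients for the species that have them (for validation/demo only).
#' @param assimilation Fraction of ingested prey energy assimilated by the
#'   predator (default 0.73).
#' @param kcal_to_kj kJ per kcal (thermochemical calorie, 4.184).
#' @return A data frame of class \code{"prey_profiles"}, one row per species,
#'   with \code{assimilation} and \code{kcal_to_kj} stored as attributes.
#' @export
#' @examples
#' pp <- prey_profiles()
#' pp$species
prey_profiles <- function(file = NULL, corrected = TRUE,
                          assimilation = 0.73, kcal_to_kj = 4.184) {
  if (is.null(file)) {
    file <- system.file("extdata", "prey_profiles.csv", package = "ectopred",
                        mustWork = TRUE)
  }
  stopifnot(assimilation > 0, assimilation <= 1, kcal_to_kj > 0)
  pp <- utils::read.csv(file, stringsAsFactors = FALSE)
  req <- c("species", "group", "length_kind", "form", "mean_mass_kg",
           "sd_mass_kg", "energy_density_kcal_g")
  missing_cols <- setdiff(req, names(pp))
  if (length(missing_cols)) {
    stop("profile table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(pp$species)) stop("duplicate species in profile table")
  if (!corrected) {
    has_printed <- !is.na(pp$printed_f_coef)
    pp$f_coef[has_printed] <- pp$printed_f_coef[has_printed]
    pp$f_extra[has_printed] <- pp$printed_f_extra[has_printed]
  }
  attr(pp, "assimilation") <- assimilation
  attr(pp, "kcal_to_kj") <- kcal_to_kj
  attr(pp, "corrected") <- corrected
  class(pp) <- c("prey_profiles", "data.frame")
  pp
}

profile_row <- function(profiles, species) {
  i <- match(species, profiles$species)
  if (is.na(i)) stop("no profile for species '", species, "'")
  profiles[i, , drop = FALSE]
}

# evaluate the stored conversion for one row at lengths (cm); sex falls back
# to the female form when unknown or when no male form is stored
eval_conversion <- function(row, length_cm, sex = "unknown") {
  if (row$length_kind == "none" || row$form == "none") {
    stop("species '", row$species, "' has no length-weight conversion")
  }
  use_male <- identical(sex, "M")
  if (row$form == "power") {
    coef_ <- if (use_male && !is.na(row$m_coef)) row$m_coef else row$f_coef
    extra <- if (use_male && !is.na(row$m_extra)) row$m_extra else row$f_extra
    expn <- if (use_male && !is.na(row$m_exp)) row$m_exp else row$f_exp
    if (is.na(extra)) extra <- 1
    coef_ * extra * (length_cm * row$length_scale)^expn
  } else {
    a <- if (use_male && !is.na(row$m_a)) row$m_a else row$f_a
    b <- if (use_male && !is.na(row$m_b)) row$m_b else row$f_b
    c_ <- if (use_male && !is.na(row$m_c)) row$m_c else row$f_c
    a * length_cm^2 + b * length_cm + c_
  }
}

#' Convert a prey length to body mass
#'
#' Applies the species' stored sex-specific length-weight conversion. When
#' the sex is unknown (or no male form exists) the female form is used.
#' Predicted masses below \code{floor_kg} (possible for quadratic forms at
#' short lengths) are clamped with a warning.
#'
#' @param profiles A \code{"prey_profiles"} table.
#' @param species Species identifier (one of \code{profiles$species}).
#' @param length_cm Length in cm (total length or disc width per the
#'   species' \code{length_kind}); vectorized.
#' @param sex \code{"F"}, \code{"M"} or \code{"unknown"}.
#' @param floor_kg Minimum mass returned (default 1 g).
#' @return Body mass in kg.
#' @export
#' @examples
#' pp <- prey_profiles()
#' mass_from_length(pp, "melbourne_skate", 87)
mass_from_length <- function(profiles, species, length_cm, sex = "unknown",
                             floor_kg = 0.001) {
  stopifnot(inherits(profiles, "prey_profiles"))
  row <- profile_row(profiles, species)
  stopifnot(is.numeric(length_cm), all(length_cm > 0))
  m <- eval_conversion(row, length_cm, sex)
  if (any(m < floor_kg)) {
    warning("predicted mass below floor for '", species, "'; clamped to ",
            floor_kg, " kg")
    m <- pmax(m, floor_kg)
  }
  m
}

#' Assimilable energy content of one prey individual
#'
#' Energy available to the predator from consuming a whole prey individual:
#' tissue energy density (kcal/g wet mass) times body mass, converted to kJ
#' and multiplied by the assimilation efficiency.
#'
#' @inheritParams mass_from_length
#' @param mass_kg Body mass in kg; defaults to the species' mean mass.
#' @return Energy in kJ (vectorized over \code{mass_kg}).
#' @export
#' @examples
#' pp <- prey_profiles()
#' available_energy(pp, "gummy_shark")  # ~8247 kJ for a 1.8 kg individual
available_energy <- function(profiles, species, mass_kg = NULL) {
  stopifnot(inherits(profiles, "prey_profiles"))
  row <- profile_row(profiles, species)
  if (is.null(mass_kg)) mass_kg <- row$mean_mass_kg
  stopifnot(all(mass_kg >= 0))
  if (is.na(row$energy_density_kcal_g)) {
    stop("no energy density for species '", species, "'")
  }
  row$energy_density_kcal_g * attr(profiles, "kcal_to_kj") *
    mass_kg * 1000 * attr(profiles, "assimilation")
}

#' Validate length-weight conversions against reported mean masses
#'
#' Guards against transcription errors in conversion coefficients: for each
#' profile with a conversion, the conversion is evaluated at the reported
#' mean length (female form) and compared with the reported mean mass. A
#' profile whose predicted/reported ratio falls outside
#' \code{[1/factor, factor]} is flagged; species without length data are
#' reported as \code{"no_conversion"} and skipped.
#'
#' @param profiles A \code{"prey_profiles"} table.
#' @param factor Flagging threshold (default 2: predicted mass within a
#'   factor of two of the reported mean).
#' @return Data frame of class \code{"profile_validation"} with columns
#'   \code{species}, \code{predicted_kg}, \code{reported_kg}, \code{ratio},
#'   \code{status} (\code{"pass"}, \code{"flag"}, \code{"no_conversion"}).
#' @export
validate_profiles <- function(profiles, factor = 2) {
  stopifnot(inherits(profiles, "prey_profiles"), factor > 1)
  out <- lapply(seq_len(nrow(profiles)), function(i) {
    row <- profiles[i, , drop = FALSE]
    if (row$length_kind == "none" || row$form == "none") {
      return(data.frame(species = row$species, predicted_kg = NA_real_,
                        reported_kg = row$mean_mass_kg, ratio = NA_real_,
                        status = "no_conversion"))
    }
    pred <- eval_conversion(row, row$mean_length_cm, sex = "F")
    ratio <- pred / row$mean_mass_kg
    ok <- is.finite(ratio) && ratio >= 1 / factor && ratio <= factor
    data.frame(species = row$species, predicted_kg = pred,
               reported_kg = row$mean_mass_kg, ratio = ratio,
               status = if (ok) "pass" else "flag")
  })
  res <- do.call(rbind, out)
  class(res) <- c("profile_validation", "data.frame")
  res
}

#' @export
print.profile_validation <- function(x, ...) {
  cat("Length-weight conversion validation (",
      sum(x$status == "pass"), " pass, ",
      sum(x$status == "flag"), " flagged, ",
      sum(x$status == "no_conversion"), " without conversion)\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
print.prey_profiles <- function(x, ...) {
  cat("Prey profile table:", nrow(x), "species/groups",
      if (isTRUE(attr(x, "corrected"))) "(corrected conversions)"
      else "(printed conversions)", "\n")
  print.data.frame(x[, c("species", "group", "length_kind", "form",
                         "mean_mass_kg", "energy_density_kcal_g")],
                   row.names = FALSE)
  invisible(x)
}
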