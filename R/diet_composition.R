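#' Diet composition object
#'
#' Per-species diet fractions \eqn{F_x} under one of three indices:
#' variant 1, frequency of occurrence (each fraction stands alone and the
#' set need not sum to one); variant 2, percent weight; variant 3,
#' count-times-average-weight. Variants 2 and 3 are compositional and must
#' sum to one.
#'
#' @param variant Integer 1, 2 or 3.
#' @param fractions Named numeric vector, species -> fraction in [0, 1].
#' @param n_stomachs Number of stomachs the estimate is based on.
#' @return List of class \code{"diet_composition"}.
#' @export
diet_composition <- function(variant, fractions, n_stomachs = NA_integer_) {
  stopifnot(variant %in% 1:3, is.numeric(fractions),
            !is.null(names(fractions)),
            all(fractions >= 0), all(fractions <= 1))
  if (variant %in% c(2, 3) && length(fractions) &&
      abs(sum(fractions) - 1) > 1e-9) {
    stop("variant ", variant, " fractions must sum to 1 (got ",
         format(sum(fractions), digits = 12), ")")
  }
  structure(list(variant = as.integer(variant), fractions = fractions,
                 n_stomachs = n_stomachs),
            class = "diet_composition")
}

#' @export
print.diet_composition <- function(x, ...) {
  cat("Diet composition, variant", x$variant,
      switch(x$variant, "(frequency of occurrence)", "(percent weight)",
             "(count x average weight)"),
      "from", x$n_stomachs, "stomachs\n")
  print(round(sort(x$fractions, decreasing = TRUE), 4))
  invisible(x)
}

check_records <- function(records) {
  req <- c("shark_id", "species")
  if (!all(req %in% names(records))) {
    stop("stomach records need columns: ", paste(req, collapse = ", "))
  }
}

#' Diet variant 1: frequency of occurrence
#'
#' The fraction of flushed stomachs in which each species occurs. The
#' denominator is the total number of stomachs flushed (including empty
#' ones), not the number of records; by default it is taken from the
#' \code{"n_stomachs"} attribute of the record table.
#'
#' @param records Stomach record data frame (\code{shark_id},
#'   \code{species}).
#' @param n_stomachs_total Denominator; must be at least the number of
#'   distinct stomachs in \code{records}.
#' @return A variant-1 [diet_composition()].
#' @export
frequency_of_occurrence <- function(records,
                                    n_stomachs_total =
                                      attr(records, "n_stomachs")) {
  check_records(records)
  if (is.null(n_stomachs_total) || is.na(n_stomachs_total) ||
      n_stomachs_total <= 0) {
    stop("n_stomachs_total must be a positive count")
  }
  n_distinct <- length(unique(records$shark_id))
  if (n_stomachs_total < n_distinct) {
    stop("n_stomachs_total (", n_stomachs_total,
         ") smaller than the number of distinct stomachs (", n_distinct, ")")
  }
  occ <- tapply(records$shark_id, records$species,
                function(id) length(unique(id)))
  fr <- as.numeric(occ) / n_stomachs_total
  names(fr) <- names(occ)
  diet_composition(1, fr, n_stomachs_total)
}

#' Diet variant 2: percent weight
#'
#' Each species' summed partly digested weight divided by the grand total
#' partly digested weight of all prey in all stomachs.
#'
#' @param records Stomach record data frame with
#'   \code{partly_digested_weight_g}.
#' @return A variant-2 [diet_composition()].
#' @export
percent_weight <- function(records) {
  check_records(records)
  if (!"partly_digested_weight_g" %in% names(records)) {
    stop("records need partly_digested_weight_g")
  }
  w <- tapply(records$partly_digested_weight_g, records$species, sum)
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0) stop("total partly digested weight is zero")
  fr <- as.numeric(w) / tot
  names(fr) <- names(w)
  diet_composition(2, fr, length(unique(records$shark_id)))
}

#' Diet variant 3: count times average weight
#'
#' Each species' total individual count across stomachs times its average
#' body mass (from the profile table), normalized over species. With equal
#' mean masses this reduces to percent-number composition.
#'
#' @param records Stomach record data frame with \code{count}.
#' @param profiles A [prey_profiles()] table with a mean mass for every
#'   species present in \code{records}.
#' @return A variant-3 [diet_composition()].
#' @export
count_avg_weight <- function(records, profiles) {
  check_records(records)
  stopifnot(inherits(profiles, "prey_profiles"))
  if (!"count" %in% names(records)) stop("records need count")
  stopifnot(all(records$count >= 1))
  cnt <- tapply(records$count, records$species, sum)
  mm <- profiles$mean_mass_kg[match(names(cnt), profiles$species)]
  if (anyNA(mm)) {
    stop("species without a profile mean mass: ",
         paste(names(cnt)[is.na(mm)], collapse = ", "))
  }
  prod <- as.numeric(cnt) * mm
  fr <- prod / sum(prod)
  names(fr) <- names(cnt)
  diet_composition(3, fr, length(unique(records$shark_id)))
}

# bootstrap resample whole stomachs (by shark_id) with replacement,
# preserving the per-stomach record structure; used for per-draw diet
# composition uncertainty
bootstrap_stomachs <- function(records, n_stomachs_total = NULL) {
  ids <- unique(records$shark_id)
  pick <- sample(ids, length(ids), replace = TRUE)
  idx <- split(seq_len(nrow(records)), records$shark_id)
  rows <- unlist(idx[as.character(pick)], use.names = FALSE)
  out <- records[rows, , drop = FALSE]
  # resampled stomachs get fresh ids so distinct-stomach counts are right
  out$shark_id <- rep(seq_along(pick),
                      lengths(idx[as.character(pick)]))
  attr(out, "n_stomachs") <- if (is.null(n_stomachs_total))
    attr(records, "n_stomachs") else n_stomachs_total
  out
}
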