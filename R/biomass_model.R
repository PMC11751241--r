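#' Linear biomass correction model
#'
#' Feeding-trial regressions convert one scat's worth of a prey species into
#' kilograms of that prey consumed: Y = intercept + slope * X, where X is
#' the prey's mean body mass (kg). Hair abundance per unit body makes small
#' prey over-counted in scats; weighting occurrences by Y corrects this.
#'
#' @param predator predator label the model applies to.
#' @param intercept regression intercept (kg per occurrence).
#' @param slope regression slope (kg consumed per kg prey mass).
#' @return object of class `biomass_model`.
#' @export
biomass_model <- function(predator, intercept, slope) {
  stopifnot(is.numeric(intercept), is.numeric(slope))
  structure(list(predator = canonical_name(predator),
                 intercept = intercept, slope = slope),
            class = "biomass_model")
}

#' Default correction models
#'
#' The felid model Y = 1.980 + 0.035 X (from cougar feeding trials) for the
#' snow leopard and the canid model Y = 0.439 + 0.008 X (wolf feeding
#' trials) for the wolf.
#'
#' @return named list of `biomass_model` objects.
#' @export
default_correction_models <- function() {
  list(snow_leopard = biomass_model("snow_leopard", 1.980, 0.035),
       wolf = biomass_model("wolf", 0.439, 0.008))
}

#' Evaluate a correction factor
#'
#' @param model a `biomass_model`.
#' @param mass prey mean body mass X in kg (vectorized); must be
#'   non-negative.
#' @return Y = intercept + slope * mass, in kg consumed per occurrence.
#' @examples
#' correction_factor(default_correction_models()$wolf, 0)    # 0.439
#' correction_factor(default_correction_models()$snow_leopard, 55)
#' @export
correction_factor <- function(model, mass) {
  stopifnot(inherits(model, "biomass_model"))
  if (any(mass < 0)) stop("prey mass must be non-negative")
  model$intercept + model$slope * mass
}

#' Relative biomass profile
#'
#' RB_i = 100 * FO_i * Y_i / sum_j FO_j * Y_j, where FO is the occurrence
#' frequency (counts or percents; the ratio is invariant to rescaling) and
#' Y_i the correction factor at prey i's mean mass. Collapses to RFO when
#' all Y_i are equal.
#'
#' @param freq a `frequency_table`, or a named numeric vector of occurrence
#'   frequencies (counts or percents).
#' @param model a `biomass_model`.
#' @param attributes prey-attributes data.frame with `species` and
#'   `mean_mass_kg` for every prey present in `freq`.
#' @return a `diet_profile` with basis `"biomass"`.
#' @export
relative_biomass <- function(freq, model, attributes) {
  if (inherits(freq, "frequency_table")) {
    fo <- freq$counts
    predator <- freq$predator
  } else {
    fo <- freq
    predator <- model$predator
  }
  fo <- fo[fo > 0]
  if (length(fo) == 0L) stop("no prey with positive occurrence frequency")
  idx <- match(names(fo), attributes$species)
  mass <- attributes$mean_mass_kg[idx]
  bad <- names(fo)[is.na(idx) | is.na(mass)]
  if (length(bad) > 0L)
    stop("missing mean mass for prey species: ", paste(bad, collapse = ", "))
  y <- correction_factor(model, mass)
  if (any(y <= 0))
    stop("correction factor non-positive for: ",
         paste(names(fo)[y <= 0], collapse = ", "))
  diet_profile(fo * y, predator = predator, basis = "biomass")
}
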