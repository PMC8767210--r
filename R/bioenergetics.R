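# Mass and energy accounting: onshore-fasting corrections to census
# masses, lipid/protein energy conversion, and the eight trip-level
# foraging-success metrics.

#' Tissue energy constants
#'
#' Adipose tissue is 90% lipid and lean tissue 27% protein; gross energy
#' when mobilized is 37.3 kJ/g for lipid and 23.5 kJ/g for protein.
#'
#' @return list with `lipid_kj_g`, `protein_kj_g`, `adipose_lipid_frac`,
#'   `lean_protein_frac`.
#' @export
energy_constants <- function() {
  list(lipid_kj_g = 37.3, protein_kj_g = 23.5,
       adipose_lipid_frac = 0.90, lean_protein_frac = 0.27)
}

#' Male onshore metabolic model
#'
#' Daily energy expenditure is `multiplier x basal_kj x mass^0.75` with a
#' multiplier of 2 during the moult and 3.1 during the breeding season,
#' converted to mass loss through the fasting fuel mix (fraction of energy
#' from lipid vs protein).
#'
#' @param basal_kj Kleiber basal coefficient (kJ/day per kg^0.75).
#' @param mult_moult,mult_breeding metabolic multipliers.
#' @param fuel_lipid_frac fraction of fasting energy from lipid; the rest
#'   is protein.
#' @return parameter list.
#' @export
male_onshore_model <- function(basal_kj = 293.1, mult_moult = 2,
                               mult_breeding = 3.1, fuel_lipid_frac = 0.93) {
  stopifnot(mult_moult >= 1, mult_breeding >= 1,
            fuel_lipid_frac >= 0, fuel_lipid_frac <= 1)
  list(basal_kj = basal_kj, exponent = 0.75, mult_moult = mult_moult,
       mult_breeding = mult_breeding, fuel_lipid_frac = fuel_lipid_frac)
}

#' Female onshore mass-change model
#'
#' Daily mass loss (kg/day) = `intercept + slope x mass`.
#'
#' @param intercept kg/day (default 0.51).
#' @param slope per day (default 0.0076).
#' @return parameter list.
#' @export
female_onshore_model <- function(intercept = 0.51, slope = 0.0076) {
  stopifnot(slope >= 0)
  list(intercept = intercept, slope = slope)
}

#' Onshore mass correction for a female
#'
#' Reconstructs the mass lost between arrival and the census by running
#' the daily loss model backwards from the census mass, day by day on the
#' changing mass. For post-moult arrivals the pup's mass is added back to
#' the female before correcting.
#'
#' @param census_mass_kg mass at the census (kg).
#' @param days_ashore whole days between arrival and census.
#' @param pup_mass_kg pup mass to add back (0 if none).
#' @param model a [female_onshore_model()].
#' @return the mass correction (kg) to add to the census mass; 0 when
#'   `days_ashore = 0` (pup mass is reported separately).
#' @export
female_onshore_mass_change <- function(census_mass_kg, days_ashore,
                                       pup_mass_kg = 0,
                                       model = female_onshore_model()) {
  stopifnot(census_mass_kg > 0)
  if (days_ashore < 0) stop("days_ashore must be >= 0")
  m <- census_mass_kg + pup_mass_kg
  for (d in seq_len(days_ashore)) m <- m + model$intercept + model$slope * m
  m - (census_mass_kg + pup_mass_kg)
}

#' Onshore mass correction for a male
#'
#' Daily energy expenditure from the allometric model, converted to mass
#' through the fasting fuel mix, iterated backwards day by day from the
#' census mass.
#'
#' @param census_mass_kg mass at the census (kg).
#' @param phase `"moult"` or `"breeding"`.
#' @param days_ashore whole days between arrival and census.
#' @param model a [male_onshore_model()].
#' @param constants [energy_constants()].
#' @return the mass correction (kg).
#' @export
male_onshore_mass_change <- function(census_mass_kg, phase, days_ashore,
                                     model = male_onshore_model(),
                                     constants = energy_constants()) {
  stopifnot(census_mass_kg > 0)
  if (days_ashore < 0) stop("days_ashore must be >= 0")
  mult <- switch(phase, moult = model$mult_moult,
                 breeding = model$mult_breeding,
                 stop("unknown phase: ", phase))
  g_per_kj <- model$fuel_lipid_frac / constants$lipid_kj_g +
    (1 - model$fuel_lipid_frac) / constants$protein_kj_g
  m <- census_mass_kg
  for (d in seq_len(days_ashore)) {
    e_kj <- mult * model$basal_kj * m^model$exponent
    m <- m + e_kj * g_per_kj / 1000
  }
  m - census_mass_kg
}

#' Energy content of a tissue gain
#'
#' `E (MJ) = 1e-3 x (0.90 x adipose_g x 37.3 + 0.27 x lean_g x 23.5)`.
#' Gains may be negative (losses).
#'
#' @param adipose_kg,lean_kg tissue mass changes (kg).
#' @param constants [energy_constants()].
#' @return energy in MJ.
#' @export
energy_gain <- function(adipose_kg, lean_kg, constants = energy_constants()) {
  (constants$adipose_lipid_frac * adipose_kg * 1000 * constants$lipid_kj_g +
   constants$lean_protein_frac * lean_kg * 1000 * constants$protein_kj_g) / 1000
}

#' Trip-level foraging-success metrics
#'
#' The eight metrics: departure mass, corrected mass gain, mass-gain rate
#' over the trip and relative to feeding time, proportional mass gain,
#' energy gain, and energy-gain rate over the trip and relative to
#' feeding time. Feeding days = proportion of time feeding x trip days.
#'
#' @param departure_mass_kg mass at departure (kg).
#' @param gain_kg onshore-corrected mass gain over the trip (kg).
#' @param trip_days trip duration (days).
#' @param feeding_days days classified as feeding (> 0 for the relative
#'   rates; otherwise they are NA).
#' @param adipose_frac fraction of the gain that is adipose tissue; the
#'   rest is lean.
#' @param constants [energy_constants()].
#' @return one-row data.frame (class `energy_budget`) with the eight
#'   metrics.
#' @export
foraging_success <- function(departure_mass_kg, gain_kg, trip_days,
                             feeding_days, adipose_frac,
                             constants = energy_constants()) {
  stopifnot(departure_mass_kg > 0, trip_days > 0, feeding_days <= trip_days,
            adipose_frac >= 0, adipose_frac <= 1)
  e <- energy_gain(gain_kg * adipose_frac, gain_kg * (1 - adipose_frac),
                   constants)
  rel <- function(x) if (feeding_days > 0) x / feeding_days else NA_real_
  out <- data.frame(departure_mass_kg = departure_mass_kg,
                    mass_gain_kg = gain_kg,
                    mass_gain_rate_kg_d = gain_kg / trip_days,
                    mass_gain_rate_feeding_kg_d = rel(gain_kg),
                    prop_mass_gain = gain_kg / departure_mass_kg,
                    energy_gain_mj = e,
                    energy_gain_rate_mj_d = e / trip_days,
                    energy_gain_rate_feeding_mj_d = rel(e))
  class(out) <- c("energy_budget", class(out))
  out
}

#' Energy budget for one simulated body record
#'
#' Applies the sex-appropriate onshore correction to the arrival census
#' mass and assembles the trip's [foraging_success()] row.
#'
#' @param body one row of a cohort's `body` table.
#' @param feeding_days feeding days from the trip summary.
#' @param sex `"male"` or `"female"`.
#' @return an `energy_budget` row with `id`.
#' @export
energy_budget <- function(body, feeding_days, sex) {
  corr <- if (sex == "female") {
    female_onshore_mass_change(body$arrival_census_mass_kg,
                               body$days_ashore_arrival, body$pup_mass_kg)
  } else {
    # males moult after the post-breeding trip and breed after the
    # post-moult trip, so the arrival haul-out phase is the other season
    male_onshore_mass_change(body$arrival_census_mass_kg,
                             if (body$trip == "post-breeding") "moult"
                             else "breeding",
                             body$days_ashore_arrival)
  }
  arrival_mass <- body$arrival_census_mass_kg + body$pup_mass_kg + corr
  gain <- arrival_mass - body$departure_mass_kg
  cbind(id = body$id,
        foraging_success(body$departure_mass_kg, gain, body$trip_days,
                         feeding_days, body$adipose_frac))
}
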