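## Simplified soil: a single-layer water bucket and a mineral-nitrogen pool
## fed by first-order mineralization of above- and belowground litter.
## The interface to the plant model is one water supply (mm d^-1) and one
## nitrogen supply (g m^-2 d^-1) against the community's daily demands, so a
## full multi-pool soil model can drop in behind the same contract.

#' Construct a soil state
#'
#' @param water_capacity plant-available water holding capacity (mm).
#' @param water current soil water (mm), defaults to capacity.
#' @param mineral_N plant-available mineral nitrogen (g m^-2).
#' @param litter_above,litter_below litter pools, each `c(mass, N)` in
#'   g m^-2 (dry matter and nitrogen).
#' @param mineralization_rate first-order litter decay / N release rate (d^-1).
#' @param n_deposition external mineral-N input (g m^-2 d^-1): atmospheric
#'   deposition plus the net mineralization of soil organic matter that the
#'   full soil model this bucket stands in for would supply.
#' @return An object of class `soil_state`.
#' @export
soil_state <- function(water_capacity = 120, water = water_capacity,
                       mineral_N = 5,
                       litter_above = c(mass = 0, N = 0),
                       litter_below = c(mass = 0, N = 0),
                       mineralization_rate = 0.02,
                       n_deposition = 0.03) {
  stopifnot(water_capacity > 0, water >= 0, water <= water_capacity,
            mineral_N >= 0, all(litter_above >= 0), all(litter_below >= 0),
            mineralization_rate >= 0, mineralization_rate <= 1,
            n_deposition >= 0)
  structure(list(water = water, water_capacity = water_capacity,
                 mineral_N = mineral_N,
                 litter_above = c(mass = unname(litter_above[1]),
                                  N = unname(litter_above[2])),
                 litter_below = c(mass = unname(litter_below[1]),
                                  N = unname(litter_below[2])),
                 mineralization_rate = mineralization_rate,
                 n_deposition = n_deposition),
            class = "soil_state")
}

#' One day of the soil water bucket
#'
#' Bare-soil evaporation takes a configurable share of PET first, then the
#' transpiration demand is supplied from what is available, and water beyond
#' capacity drains. The balance
#' `precip - evaporation - supply - drainage = change in storage`
#' closes exactly.
#'
#' @param soil a `soil_state`.
#' @param day one row of a climate data frame (needs `precip_mm`, `pet_mm`).
#' @param transpiration_demand community water demand (mm, >= 0).
#' @param pet_soil_share fraction of PET taken by bare-soil evaporation.
#' @return A list `(soil, water_supply, evaporation, drainage)`.
#' @export
soil_water_step <- function(soil, day, transpiration_demand,
                            pet_soil_share = 0.3) {
  stopifnot(transpiration_demand >= 0)
  evap <- min(pet_soil_share * day$pet_mm, soil$water + day$precip_mm)
  avail <- soil$water + day$precip_mm - evap
  supply <- min(transpiration_demand, avail)
  w2 <- avail - supply
  drain <- max(0, w2 - soil$water_capacity)
  soil$water <- w2 - drain
  list(soil = soil, water_supply = supply, evaporation = evap,
       drainage = drain)
}

#' One day of litter decay and mineral nitrogen
#'
#' Fresh litter (mass and nitrogen) enters the above/below pools; a fixed
#' fraction `mineralization_rate` of each pool decays per day, releasing the
#' pool nitrogen to the mineral pool; atmospheric deposition adds to it; the
#' plant demand is supplied from the mineral stock. Total nitrogen
#' (mineral + litter + cumulative supplied - cumulative deposited -
#' cumulative litter input) is conserved.
#'
#' @param soil a `soil_state`.
#' @param litter_in named list/vector with `above_mass`, `above_N`,
#'   `below_mass`, `below_N` (g m^-2, >= 0).
#' @param n_demand community nitrogen demand (g m^-2, >= 0).
#' @return A list `(soil, n_supply, mineralized_N)`.
#' @export
soil_nitrogen_step <- function(soil, litter_in = c(above_mass = 0, above_N = 0,
                                                   below_mass = 0, below_N = 0),
                               n_demand = 0) {
  li <- as.list(litter_in)
  stopifnot(n_demand >= 0, all(unlist(li) >= 0))
  soil$litter_above["mass"] <- soil$litter_above[["mass"]] + li$above_mass
  soil$litter_above["N"]    <- soil$litter_above[["N"]] + li$above_N
  soil$litter_below["mass"] <- soil$litter_below[["mass"]] + li$below_mass
  soil$litter_below["N"]    <- soil$litter_below[["N"]] + li$below_N
  r <- soil$mineralization_rate
  mineralized <- r * (soil$litter_above[["N"]] + soil$litter_below[["N"]])
  soil$litter_above <- soil$litter_above * (1 - r)
  soil$litter_below <- soil$litter_below * (1 - r)
  soil$mineral_N <- soil$mineral_N + mineralized + soil$n_deposition
  supply <- min(n_demand, soil$mineral_N)
  soil$mineral_N <- soil$mineral_N - supply
  list(soil = soil, n_supply = supply, mineralized_N = mineralized)
}
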