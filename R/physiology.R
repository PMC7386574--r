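## Plant physiology: leaf light response, canopy shading, the gap-model
## closed form for whole-plant gross photosynthesis, growth limitation by
## temperature / water / nitrogen, and the daily carbon bookkeeping.

#' Saturating leaf light response
#'
#' Gross leaf photosynthesis `p(I) = alpha * I * p_max / (alpha * I + p_max)`:
#' initial slope `alpha`, asymptote `p_max`, half-saturation at
#' `I = p_max / alpha`.
#'
#' @param I photosynthetically active irradiance at the leaf
#'   (umol photons m^-2 s^-1, >= 0; vectorized).
#' @param traits a `species_traits` (uses `p_max`, `alpha`).
#' @return Gross leaf photosynthesis, umol CO2 m^-2 s^-1.
#' @export
leaf_light_response <- function(I, traits) {
  stopifnot(all(I >= 0))
  traits$alpha * I * traits$p_max / (traits$alpha * I + traits$p_max)
}

#' Vertical light profile through the canopy
#'
#' Each plant's leaf area is spread uniformly over its own height; the
#' attenuation above height `z` sums every plant's own extinction coefficient
#' times its leaf area above `z` (species-specific Beer-Lambert):
#' `I(z) = par_top * exp(-K(z))` with
#' `K(z) = sum_j k_j * LA_j * max(0, h_j - z) / h_j / patch_area`.
#' Because the per-plant leaf area density is uniform, `K` is piecewise linear
#' in `z` and is evaluated exactly (the fine-layer limit of a discretized
#' canopy); `layer_height` only sets the grid of the returned profile.
#'
#' @param plants a data frame with columns `species`, `height`, `shoot_green`
#'   (one row per plant); widths are not needed for shading.
#' @param traits_list named list of `species_traits`, names matching
#'   `plants$species`.
#' @param par_top irradiance above the canopy (umol photons m^-2 s^-1).
#' @param patch_area patch ground area, cm^2.
#' @param layer_height grid spacing of the returned profile, cm.
#' @return A list with `plant_irradiance` (irradiance at each plant's top, in
#'   input row order) and `profile` (data frame `z`, `K_above`, `irradiance`).
#' @export
canopy_light_profile <- function(plants, traits_list, par_top,
                                 patch_area = 10000, layer_height = 1) {
  n <- nrow(plants)
  if (is.null(n) || n == 0L) {
    z <- seq(0, 1, by = layer_height)
    return(list(plant_irradiance = numeric(0),
                profile = data.frame(z = z, K_above = 0, irradiance = par_top)))
  }
  k <- vapply(plants$species, function(s) traits_list[[s]]$k, numeric(1))
  SLA <- vapply(plants$species, function(s) traits_list[[s]]$SLA, numeric(1))
  la <- SLA * plants$shoot_green
  h <- plants$height
  a <- ifelse(h > 0, k * la / (patch_area * h), 0)  # extinction per cm height
  K_above <- function(z) {
    vapply(z, function(zz) sum(a * pmax(0, h - zz)), numeric(1))
  }
  # irradiance at each plant's top: only plants strictly taller shade it
  Ki <- vapply(seq_len(n), function(i) sum(a * pmax(0, h - h[i])), numeric(1))
  zmax <- max(h)
  z <- seq(0, max(zmax, layer_height), by = layer_height)
  Kz <- K_above(z)
  list(plant_irradiance = par_top * exp(-Ki),
       profile = data.frame(z = z, K_above = Kz, irradiance = par_top * exp(-Kz)))
}

#' Whole-plant daily gross photosynthesis (closed form)
#'
#' Integrates the leaf light response over the plant's own leaf area index
#' `LAI_ind = leaf_area / cover_area` under within-crown Beer-Lambert
#' extinction with transmission `m`:
#' \deqn{P_{area} = \frac{p_{max}}{k}\,\ln\!\frac{\alpha k I + p_{max}(1-m)}
#'   {\alpha k I e^{-k\,LAI_{ind}} + p_{max}(1-m)}}
#' in umol CO2 per m^2 covered ground per second, then converts to g ODM per
#' day via the covered area, the day length, 44e-6 g CO2 per umol and the
#' ODM-per-CO2 yield.
#'
#' @param plant a `plant_state`.
#' @param I_top irradiance at the plant's top (umol photons m^-2 s^-1).
#' @param traits its `species_traits`.
#' @param daylength day length in hours.
#' @param odm_per_co2 g organic dry matter formed per g CO2 assimilated.
#' @return Gross production, g ODM d^-1.
#' @export
plant_gross_photosynthesis <- function(plant, I_top, traits, daylength,
                                       odm_per_co2 = 0.63) {
  areas <- plant_areas(plant, traits)
  cover <- areas[["cover_area"]]
  if (cover <= 0 || areas[["leaf_area"]] <= 0 || I_top <= 0) return(0)
  lai_ind <- areas[["leaf_area"]] / cover
  p_area <- photosynthesis_area_rate(I_top, lai_ind, traits)
  p_area * (cover / 1e4) * daylength * 3600 * 44e-6 * odm_per_co2
}

# P per m^2 covered ground (umol CO2 m^-2 s^-1); shared by R and tests.
photosynthesis_area_rate <- function(I_top, lai_ind, traits) {
  aki <- traits$alpha * traits$k * I_top
  pm1 <- traits$p_max * (1 - traits$m)
  (traits$p_max / traits$k) *
    log((aki + pm1) / (aki * exp(-traits$k * lai_ind) + pm1))
}

#' Growth limitation factors
#'
#' Temperature limitation ramps linearly from 0 at `T0` to 1 at `T1`
#' (defaults 0 and 10 degC); water and nitrogen limitation equal the
#' (previous day's) supply/demand ratios. All factors are clamped to \[0, 1\]
#' and multiply gross production.
#'
#' @param day one climate row (needs `tmean_C`).
#' @param water_supply_ratio,n_supply_ratio supply/demand ratios in \[0, 1\].
#' @param T0,T1 temperature ramp endpoints (degC).
#' @return A named list `f_temp`, `f_water`, `f_nitrogen`.
#' @export
limitation_factors <- function(day, water_supply_ratio = 1, n_supply_ratio = 1,
                               T0 = 0, T1 = 10) {
  stopifnot(water_supply_ratio >= 0, water_supply_ratio <= 1,
            n_supply_ratio >= 0, n_supply_ratio <= 1, T1 > T0)
  list(f_temp = min(1, max(0, (day$tmean_C - T0) / (T1 - T0))),
       f_water = water_supply_ratio,
       f_nitrogen = n_supply_ratio)
}

#' One day of plant carbon bookkeeping
#'
#' Applies the limitation factors to gross production, subtracts maintenance
#' respiration `r_m * (shoot_green + root)` and growth respiration (fraction
#' `r_g` of the surplus), allocates net production between shoot
#' (`alloc_shoot`) and root, transfers senescing tissue
#' (green shoot at rate `1/LLS` to the senescent pool, senescent shoot at
#' `litter_fall_rate` to aboveground litter, root at `1/RLS` to belowground
#' litter), and updates the cylinder dimensions. A negative balance
#' (`gpp_lim < Rm`) shrinks the respiring pools proportionally; if they cannot
#' cover the deficit the plant dies and its pools go to litter. Carbon is
#' conserved exactly:
#' `delta(pools) + litter out + respiration = gpp_lim`.
#'
#' Water demand is `gpp_lim / WUE` (kg = mm on 1 m^2) and nitrogen demand
#' `npp / CN_green` (g m^-2).
#'
#' @param plant a `plant_state`.
#' @param gpp unlimited gross production from
#'   [plant_gross_photosynthesis()], g ODM.
#' @param lim limitation factors from [limitation_factors()].
#' @param traits its `species_traits`.
#' @param litter_fall_rate daily rate at which standing senescent shoot falls
#'   to litter (d^-1).
#' @return A list with the updated `plant`, `litter` (named vector
#'   `above_mass`, `above_N`, `below_mass`, `below_N`), `respiration` (g),
#'   `gpp_lim` (g), `water_demand` (kg) and `n_demand` (g).
#' @export
daily_carbon_update <- function(plant, gpp, lim, traits,
                                litter_fall_rate = 0.03) {
  stopifnot(gpp >= 0)
  gpp_lim <- gpp * lim$f_temp * lim$f_water * lim$f_nitrogen
  Rm <- traits$r_m * (plant$shoot_green + plant$root)
  litter <- c(above_mass = 0, above_N = 0, below_mass = 0, below_N = 0)
  if (gpp_lim >= Rm) {
    surplus <- gpp_lim - Rm
    npp <- (1 - traits$r_g) * surplus
    respiration <- Rm + traits$r_g * surplus
    plant$shoot_green <- plant$shoot_green + traits$alloc_shoot * npp
    plant$root <- plant$root + (1 - traits$alloc_shoot) * npp
  } else {
    npp <- 0
    deficit <- Rm - gpp_lim
    live <- plant$shoot_green + plant$root
    if (deficit >= live) {            # starved outright
      respiration <- gpp_lim + live
      litter["above_mass"] <- plant$shoot_senescent
      litter["above_N"] <- plant$shoot_senescent / traits$CN_sen
      plant$shoot_green <- 0; plant$root <- 0; plant$shoot_senescent <- 0
      plant$alive <- FALSE
    } else {
      respiration <- Rm
      f <- 1 - deficit / live
      plant$shoot_green <- plant$shoot_green * f
      plant$root <- plant$root * f
    }
  }
  if (plant$alive) {
    sen <- plant$shoot_green / traits$LLS
    plant$shoot_green <- plant$shoot_green - sen
    plant$shoot_senescent <- plant$shoot_senescent + sen
    fall <- plant$shoot_senescent * litter_fall_rate
    plant$shoot_senescent <- plant$shoot_senescent - fall
    rloss <- plant$root / traits$RLS
    plant$root <- plant$root - rloss
    litter["above_mass"] <- litter[["above_mass"]] + fall
    litter["above_N"] <- litter[["above_N"]] + fall / traits$CN_sen
    litter["below_mass"] <- litter[["below_mass"]] + rloss
    litter["below_N"] <- litter[["below_N"]] + rloss / traits$CN_sen
    plant$age <- plant$age + 1
    plant <- update_dimensions(plant, traits)
  } else {
    plant$height <- 0; plant$width <- 0
  }
  list(plant = plant, litter = litter, respiration = respiration,
       gpp_lim = gpp_lim, water_demand = gpp_lim / traits$WUE,
       n_demand = npp / traits$CN_green)
}
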