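## Demography: external seed rain, emergence under the space budget,
## intrinsic and crowding (self-thinning) mortality. These R-level steps
## operate on a plants data frame (one row per individual) and are the
## reference semantics of the compiled daily loop.

#' An empty plant table
#'
#' @return A zero-row data frame with the plant columns `species`, `age`,
#'   `height`, `width`, `shoot_green`, `shoot_senescent`, `root`.
#' @export
empty_plants <- function() {
  data.frame(species = character(0), age = numeric(0), height = numeric(0),
             width = numeric(0), shoot_green = numeric(0),
             shoot_senescent = numeric(0), root = numeric(0),
             stringsAsFactors = FALSE)
}

plants_exclusive_area <- function(plants, traits_list) {
  if (nrow(plants) == 0L) return(numeric(0))
  f_O <- vapply(plants$species, function(s) traits_list[[s]]$f_O, numeric(1))
  f_O * (pi / 4) * plants$width^2
}

#' Daily external seed rain
#'
#' From julian day `t_meta` on, for `seed_rain_duration` days, a cohort of
#' germinating seeds arrives with Poisson count of mean
#' `N_seed_meta * germ_pct * patch area`; it will emerge `t_em` days later.
#' Outside the window no cohort arrives.
#'
#' @param doy julian day of year.
#' @param traits a `species_traits`.
#' @param patch_area patch area in cm^2.
#' @param seed_rain_duration length of the seed-rain window, days.
#' @return A list `(species, count, emergence_day)` with `emergence_day`
#'   expressed as an offset in days from today, or `NULL` outside the window
#'   or when the Poisson draw is zero.
#' @export
seed_rain_step <- function(doy, traits, patch_area = 10000,
                           seed_rain_duration = 120) {
  if (doy < traits$t_meta || doy >= traits$t_meta + seed_rain_duration)
    return(NULL)
  count <- rpois(1, traits$N_seed_meta * traits$germ_pct * patch_area / 1e4)
  if (count == 0L) return(NULL)
  list(species = traits$species, count = count, emergence_day = traits$t_em)
}

#' Seedling emergence under the space budget
#'
#' Cohorts whose emergence day has come turn into seedlings
#' ([make_seedling()]), but only while the cumulative exclusive area of
#' standing plants plus the newcomers stays within the patch; surplus
#' seedlings are discarded and counted.
#'
#' @param cohorts list of cohorts (as from [seed_rain_step()], with
#'   `emergence_day` counted down to 0 when due).
#' @param plants current plant table.
#' @param traits_list named list of `species_traits`.
#' @param patch_area patch area, cm^2.
#' @return A list `(plants, established, discarded)`.
#' @export
emergence_step <- function(cohorts, plants, traits_list, patch_area = 10000) {
  established <- 0L; discarded <- 0L
  used <- sum(plants_exclusive_area(plants, traits_list))
  for (co in cohorts) {
    if (is.null(co) || co$emergence_day > 0) next
    tr <- traits_list[[co$species]]
    sdl <- make_seedling(tr)
    a0 <- tr$f_O * (pi / 4) * sdl$width^2
    fit <- max(0L, min(co$count, floor((patch_area - used) / a0)))
    if (fit > 0) {
      used <- used + fit * a0
      new <- data.frame(species = co$species, age = 0, height = sdl$height,
                        width = sdl$width, shoot_green = sdl$shoot_green,
                        shoot_senescent = 0, root = sdl$root,
                        stringsAsFactors = FALSE)
      plants <- rbind(plants, new[rep(1L, fit), ])
    }
    established <- established + fit
    discarded <- discarded + co$count - fit
  }
  rownames(plants) <- NULL
  list(plants = plants, established = established, discarded = discarded)
}

#' Intrinsic (and starvation) mortality
#'
#' Each plant dies independently: with daily probability `m_seed` while
#' younger than `age_rep` years, otherwise with the compounded daily
#' equivalent `1 - (1 - m_basic)^(1/365)` of the annual mature rate. Plants
#' whose green shoot has fallen below `starvation_floor` die deterministically.
#' Dead shoots go to aboveground litter, dead roots to belowground litter.
#'
#' @param plants plant table.
#' @param traits_list named list of `species_traits`.
#' @param starvation_floor minimum viable green shoot (g).
#' @return A list `(plants, litter, deaths)` with `litter` as in
#'   [daily_carbon_update()].
#' @export
mortality_step <- function(plants, traits_list, starvation_floor = 1e-4) {
  n <- nrow(plants)
  litter <- c(above_mass = 0, above_N = 0, below_mass = 0, below_N = 0)
  if (n == 0L) return(list(plants = plants, litter = litter, deaths = 0L))
  p <- vapply(seq_len(n), function(i) {
    tr <- traits_list[[plants$species[i]]]
    if (plants$age[i] < tr$age_rep * 365) tr$m_seed
    else 1 - (1 - tr$m_basic)^(1 / 365)
  }, numeric(1))
  dies <- runif(n) < p | plants$shoot_green < starvation_floor
  if (any(dies)) {
    cn <- vapply(plants$species[dies],
                 function(s) traits_list[[s]]$CN_sen, numeric(1))
    shoot <- plants$shoot_green[dies] + plants$shoot_senescent[dies]
    litter["above_mass"] <- sum(shoot)
    litter["above_N"] <- sum(shoot / cn)
    litter["below_mass"] <- sum(plants$root[dies])
    litter["below_N"] <- sum(plants$root[dies] / cn)
  }
  list(plants = plants[!dies, , drop = FALSE], litter = litter,
       deaths = sum(dies))
}

#' Crowding mortality (self-thinning)
#'
#' Triggered only when the summed exclusive area of all plants exceeds the
#' patch: plants are removed one at a time, chosen uniformly at random
#' (`bias = "uniform"`) or with probability inversely proportional to size
#' (`bias = "inverse_size"`), until the community fits again. Removed pools
#' go to litter.
#'
#' @param plants plant table.
#' @param traits_list named list of `species_traits`.
#' @param patch_area patch area, cm^2.
#' @param bias victim selection rule.
#' @return A list `(plants, litter, removed)`.
#' @export
crowding_step <- function(plants, traits_list, patch_area = 10000,
                          bias = c("uniform", "inverse_size")) {
  bias <- match.arg(bias)
  litter <- c(above_mass = 0, above_N = 0, below_mass = 0, below_N = 0)
  area <- plants_exclusive_area(plants, traits_list)
  total <- sum(area)
  if (total <= patch_area)
    return(list(plants = plants, litter = litter, removed = 0L))
  n <- nrow(plants)
  w <- if (bias == "uniform") rep(1, n)
       else 1 / pmax(plants$shoot_green + plants$shoot_senescent, 1e-9)
  ord <- sample.int(n, n, prob = w)
  # removing in this random order one by one until the constraint holds
  excess <- total - patch_area
  cum <- cumsum(area[ord])
  k <- unname(which(cum >= excess)[1])
  victims <- ord[seq_len(k)]
  cn <- vapply(plants$species[victims],
               function(s) traits_list[[s]]$CN_sen, numeric(1))
  shoot <- plants$shoot_green[victims] + plants$shoot_senescent[victims]
  litter["above_mass"] <- sum(shoot)
  litter["above_N"] <- sum(shoot / cn)
  litter["below_mass"] <- sum(plants$root[victims])
  litter["below_N"] <- sum(plants$root[victims] / cn)
  list(plants = plants[-victims, , drop = FALSE], litter = litter,
       removed = k)
}
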