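## The community simulation: configuration, the daily loop (compiled), mowing,
## censuses and aggregation of censuses into annual vegetation patterns.

#' Simulation configuration
#'
#' All patch-level knobs of the simulator with their defaults: the 1 m x 1 m
#' patch, the temperature ramp of the limitation function, the ODM-per-CO2
#' yield, the soil buckets, the seed-rain window, standing-senescent litter
#' fall, the starvation floor and the crowding victim rule.
#'
#' @param patch_area patch ground area, cm^2 (default 1 m^2).
#' @param T0,T1 temperature limitation ramp endpoints, degC.
#' @param odm_per_co2 g organic dry matter per g CO2 assimilated.
#' @param pet_soil_share share of PET taken by bare-soil evaporation.
#' @param water_capacity,water_init soil water bucket, mm.
#' @param mineral_N_init initial plant-available nitrogen, g m^-2.
#' @param mineralization_rate litter decay / N release rate, d^-1.
#' @param n_deposition external mineral-N input (deposition + net soil
#'   organic matter mineralization), g m^-2 d^-1.
#' @param seed_rain_duration length of the seed-rain window, days.
#' @param litter_fall_rate senescent-shoot fall rate, d^-1.
#' @param starvation_floor minimum viable green shoot, g.
#' @param crowding_bias `"uniform"` or `"inverse_size"` victim selection.
#' @return A named list of class `sim_config`.
#' @export
sim_config <- function(patch_area = 10000, T0 = 0, T1 = 10,
                       odm_per_co2 = 0.63, pet_soil_share = 0.3,
                       water_capacity = 120, water_init = water_capacity,
                       mineral_N_init = 5, mineralization_rate = 0.02,
                       n_deposition = 0.03, seed_rain_duration = 120,
                       litter_fall_rate = 0.03, starvation_floor = 1e-4,
                       crowding_bias = c("uniform", "inverse_size")) {
  crowding_bias <- match.arg(crowding_bias)
  structure(as.list(environment()), class = "sim_config")
}

.daily_cols <- c(
  "n_plants", "exclusive_area", "max_height", "living_mass",
  "cum_gpp", "cum_respiration", "cum_litter", "cum_harvest", "cum_recruit",
  "soil_water", "mineral_N", "litter_above_mass", "litter_above_N",
  "litter_below_mass", "litter_below_N",
  "cum_precip", "cum_evaporation", "cum_water_supply", "cum_drainage",
  "cum_litter_N", "cum_N_deposition", "cum_N_supply",
  "f_water", "f_nitrogen", "water_demand", "n_demand", "agb")

traits_matrix <- function(traits_list, config) {
  m <- t(vapply(traits_list, function(tr) c(
    tr$h_max, tr$hw, tr$f_s, tr$f_O, tr$SLA, tr$sr,
    tr$N_seed_meta, tr$t_meta, tr$t_em, tr$germ_pct, 100 * tr$h_min,
    tr$age_rep * 365, tr$LLS, tr$RLS, tr$m_seed,
    1 - (1 - tr$m_basic)^(1 / 365),
    tr$p_max, tr$alpha, tr$k, tr$m, tr$WUE, tr$CN_green, tr$CN_sen,
    tr$alloc_shoot, tr$r_m, tr$r_g), numeric(26)))
  rownames(m) <- names(traits_list)
  m
}

#' Mowing schedule for a run of years
#'
#' Twice-yearly mowing to a fixed height: in the establishment year on 11 July
#' and 20 September, in all later years on 20 June and 20 September.
#'
#' @param years number of years.
#' @param start_year first calendar year.
#' @param cut_height_cm cutting height, cm.
#' @param establishment_year is the first year the sowing year (July first
#'   cut) rather than a regular year?
#' @return A data frame `date`, `cut_height_cm`.
#' @export
make_mowing_schedule <- function(years, start_year = 2003, cut_height_cm = 10,
                                 establishment_year = FALSE) {
  ys <- start_year + seq_len(years) - 1L
  first <- ifelse(seq_along(ys) == 1L & establishment_year, "-07-11", "-06-20")
  dates <- sort(as.Date(c(paste0(ys, first), paste0(ys, "-09-20"))))
  data.frame(date = dates, cut_height_cm = cut_height_cm)
}

#' Read a mowing schedule CSV
#'
#' Columns `date` (ISO) and `cut_height_cm`.
#'
#' @param file CSV path.
#' @return A data frame `date`, `cut_height_cm`.
#' @export
read_mowing_csv <- function(file) {
  x <- read.csv(file, stringsAsFactors = FALSE)
  stopifnot(all(c("date", "cut_height_cm") %in% names(x)))
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) stop("unparseable mowing date")
  if (any(x$cut_height_cm <= 0)) stop("cut height must be positive")
  x[order(x$date), ]
}

#' Run the individual-based grassland simulation
#'
#' Simulates the daily dynamics of every plant on the patch over the span of
#' the climate series. Each day runs, in order: seed rain, emergence under the
#' space budget, the canopy light profile, gross photosynthesis with
#' temperature/water/nitrogen limitation, carbon allocation and senescence,
#' intrinsic and starvation mortality, crowding mortality, the soil water and
#' nitrogen steps, mowing (if scheduled) and a census (if scheduled). The run
#' is reproducible under a fixed seed; stochasticity enters only through seed
#' rain counts and mortality.
#'
#' @param traits a `species_traits` object or a (optionally named) list of
#'   them for multi-species communities.
#' @param climate a climate data frame (see [generate_synthetic_climate()]).
#' @param mowing a mowing schedule data frame (`date`, `cut_height_cm`), or
#'   `NULL` for no mowing.
#' @param census_dates dates at which to record a census; default is the day
#'   before each mowing event.
#' @param config a [sim_config()].
#' @param init_plants optional initial plant table (see [empty_plants()]).
#' @param seed optional integer seed (`set.seed` is called when given).
#' @return An object of class `grass_sim`: a list with `census` (one row per
#'   census date and species, plus `community` rows; columns `date`,
#'   `species`, `agb_g_m2`, `cover_pct`, `lai`, `height_cm`), `daily` (one row
#'   per day of state and cumulative-flux bookkeeping), `harvest` (per mowing
#'   event), `discarded_seeds`, `final_plants` and the inputs' metadata.
#' @export
run_simulation <- function(traits, climate, mowing = NULL, census_dates = NULL,
                           config = sim_config(), init_plants = NULL,
                           seed = NULL) {
  if (inherits(traits, "species_traits")) traits <- list(traits)
  if (is.null(names(traits)) || any(!nzchar(names(traits))))
    names(traits) <- vapply(traits, function(tr) tr$species, character(1))
  if (!is.null(seed)) set.seed(seed)
  ndays <- nrow(climate)
  if (ndays < 1L) stop("missing driver: empty climate series")
  doy <- doy365(climate$date)

  day_of <- function(dates, what) {
    idx <- match(as.Date(dates), climate$date)
    if (anyNA(idx)) stop(what, " date outside the simulated span")
    as.integer(idx)
  }
  if (!is.null(mowing) && nrow(mowing)) {
    mow_day <- day_of(mowing$date, "mowing")
    mow_height <- as.numeric(mowing$cut_height_cm)
  } else {
    mow_day <- integer(0); mow_height <- numeric(0)
  }
  if (is.null(census_dates)) {
    census_dates <- if (length(mow_day)) climate$date[pmax(1L, mow_day - 1L)]
                    else climate$date[ndays]
  }
  cens_day <- day_of(census_dates, "census")

  cfgv <- c(config$patch_area, config$T0, config$T1, config$odm_per_co2,
            config$pet_soil_share, config$water_capacity, config$water_init,
            config$mineral_N_init, config$mineralization_rate,
            config$n_deposition, config$seed_rain_duration,
            config$litter_fall_rate, config$starvation_floor,
            as.numeric(config$crowding_bias == "inverse_size"))

  ip <- NULL
  if (!is.null(init_plants) && nrow(init_plants)) {
    spi <- match(init_plants$species, names(traits))
    if (anyNA(spi)) stop("init plant species not in trait list")
    ip <- cbind(spi - 1L, init_plants$age, init_plants$height,
                init_plants$width, init_plants$shoot_green,
                init_plants$shoot_senescent, init_plants$root)
  }

  clim <- as.matrix(climate[c("tmean_C", "par_mol_m2_d", "daylength_h",
                              "precip_mm", "pet_mm")])
  res <- sim_core(traits_matrix(traits, config), clim, doy,
                  mow_day, mow_height, cens_day, cfgv, ip)

  sp_names <- names(traits)
  cens <- do.call(rbind, lapply(seq_along(cens_day), function(i) {
    rows <- data.frame(date = as.Date(census_dates[i]),
                       species = c(sp_names, "community"),
                       agb_g_m2 = c(res$census_agb[i, ], res$census_community[i, 1]),
                       cover_pct = c(res$census_cover[i, ], res$census_community[i, 2]),
                       lai = c(res$census_lai[i, ], res$census_community[i, 3]),
                       height_cm = c(res$census_height_sp[i, ], res$census_community[i, 4]),
                       stringsAsFactors = FALSE)
    rows
  }))
  cens <- cens[order(cens$date), ]
  rownames(cens) <- NULL

  daily <- as.data.frame(res$daily)
  names(daily) <- .daily_cols
  daily <- cbind(date = climate$date, day = seq_len(ndays), daily)

  # one row per cohort state with its individual count (identical plants are
  # tracked as counted states inside the compiled loop)
  fp <- as.data.frame(res$final_plants)
  if (nrow(fp)) {
    names(fp) <- c("species", "age", "height", "width", "shoot_green",
                   "shoot_senescent", "root", "count")
    fp$species <- sp_names[fp$species + 1L]
  } else {
    fp <- cbind(empty_plants(), count = numeric(0))
  }

  structure(list(census = cens, daily = daily,
                 harvest = data.frame(date = if (length(mow_day))
                     climate$date[mow_day] else as.Date(character(0)),
                   harvest_g_m2 = as.numeric(res$harvest_events) /
                     (config$patch_area / 1e4)),
                 discarded_seeds = res$discarded_seeds,
                 final_plants = fp,
                 species = sp_names, config = config, seed = seed),
            class = "grass_sim")
}

#' @export
print.grass_sim <- function(x, ...) {
  cat("<grass_sim> ", length(x$species), " species, ",
      nrow(x$daily), " days, ", length(unique(x$census$date)),
      " censuses\n", sep = "")
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  cat("  final plant states:", nrow(x$final_plants),
      "(", sum(x$final_plants$count), "individuals )\n")
  invisible(x)
}

#' Mow a plant table to a cutting height
#'
#' Every plant taller than the blade keeps the `cut_height / height` fraction
#' of both shoot pools (green and senescent cut alike), its height becomes the
#' cutting height, and its width is unchanged; shorter plants are untouched.
#' Harvested mass equals the removed shoot exactly.
#'
#' @param plants a plant table (see [empty_plants()]).
#' @param cut_height blade height, cm (> 0).
#' @return A list `(plants, harvest)` with `harvest` in g per patch.
#' @export
apply_mowing <- function(plants, cut_height) {
  stopifnot(cut_height > 0)
  if (nrow(plants) == 0L) return(list(plants = plants, harvest = 0))
  tall <- plants$height > cut_height
  frac <- ifelse(tall, cut_height / plants$height, 1)
  shoot <- plants$shoot_green + plants$shoot_senescent
  harvest <- sum(shoot * (1 - frac))
  plants$shoot_green <- plants$shoot_green * frac
  plants$shoot_senescent <- plants$shoot_senescent * frac
  plants$height[tall] <- cut_height
  list(plants = plants, harvest = harvest)
}

#' Take a census of a plant table
#'
#' Per species: summed shoot mass per ground area (AGB, g m^-2), summed
#' exclusive area as percent cover, summed leaf area over patch area (LAI)
#' and maximum plant height; plus a `community` row with totals and the
#' overall maximum height.
#'
#' @param plants a plant table.
#' @param traits_list named list of `species_traits`.
#' @param patch_area patch area, cm^2.
#' @param date census date (recorded only).
#' @return A census data frame (as in [run_simulation()]'s `census`).
#' @export
census <- function(plants, traits_list, patch_area = 10000, date = NA) {
  patch_m2 <- patch_area / 1e4
  one <- function(keep, name) {
    p <- plants[keep, , drop = FALSE]
    if (nrow(p) == 0L)
      return(data.frame(date = date, species = name, agb_g_m2 = 0,
                        cover_pct = 0, lai = 0, height_cm = 0,
                        stringsAsFactors = FALSE))
    excl <- plants_exclusive_area(p, traits_list)
    sla <- vapply(p$species, function(s) traits_list[[s]]$SLA, numeric(1))
    data.frame(date = date, species = name,
               agb_g_m2 = sum(p$shoot_green + p$shoot_senescent) / patch_m2,
               cover_pct = 100 * sum(excl) / patch_area,
               lai = sum(sla * p$shoot_green) / patch_area,
               height_cm = max(p$height), stringsAsFactors = FALSE)
  }
  rows <- lapply(names(traits_list),
                 function(s) one(plants$species == s, s))
  rows <- c(rows, list(one(rep(TRUE, nrow(plants)), "community")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Aggregate censuses to annual vegetation patterns
#'
#' Pools the (typically biannual) censuses of each calendar year into the
#' annual mean and the intra-annual (min, max) range, per species/community
#' and attribute — the granularity at which observed vegetation patterns are
#' compared with simulations.
#'
#' @param census_df a census data frame (from [run_simulation()] or
#'   [census()]).
#' @param attributes which census attributes to aggregate.
#' @return A long data frame `subject`, `attribute`, `year`, `mean`, `min`,
#'   `max`, `n_census`.
#' @export
annual_aggregate <- function(census_df,
                             attributes = c("agb_g_m2", "lai", "height_cm",
                                            "cover_pct")) {
  stopifnot(nrow(census_df) > 0)
  year <- as.integer(format(as.Date(census_df$date), "%Y"))
  out <- list()
  for (sub in unique(census_df$species)) {
    for (attr in attributes) {
      sel <- census_df$species == sub
      v <- census_df[[attr]][sel]
      ys <- year[sel]
      agg <- vapply(sort(unique(ys)), function(y) {
        vv <- v[ys == y]
        c(mean(vv), min(vv), max(vv), length(vv))
      }, numeric(4))
      out[[length(out) + 1L]] <- data.frame(
        subject = sub, attribute = attr, year = sort(unique(ys)),
        mean = agg[1, ], min = agg[2, ], max = agg[3, ],
        n_census = as.integer(agg[4, ]), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble the ten vegetation patterns of a monoculture/mixture study
#'
#' From the annual aggregates of each monoculture and of the mixture, builds
#' the ten community patterns used by the multi-constrained cost function:
#' (i) AGB, (ii) LAI, (iii) height and (iv) cover of each monoculture;
#' (v) community LAI and (vi) community height of the mixture; per-species
#' (vii) AGB and (viii) cover in the mixture; and per-species relative yields
#' of (ix) AGB and (x) cover (mixture value over monoculture value).
#'
#' @param mono named list (by species) of annual-aggregate data frames of the
#'   monoculture runs ([annual_aggregate()]).
#' @param mixture annual-aggregate data frame of the mixture run, or `NULL`
#'   for monoculture-only pattern sets.
#' @return A long data frame `pattern_id` (i–x), `subject`, `attribute`,
#'   `year`, `mean`, `min`, `max`.
#' @export
build_pattern_set <- function(mono, mixture = NULL) {
  grab <- function(df, subject, attribute, pattern_id) {
    sel <- df$subject == subject & df$attribute == attribute
    if (!any(sel)) return(NULL)
    data.frame(pattern_id = pattern_id, subject = subject,
               attribute = attribute, year = df$year[sel],
               mean = df$mean[sel], min = df$min[sel], max = df$max[sel],
               stringsAsFactors = FALSE)
  }
  ids <- c(agb_g_m2 = "i", lai = "ii", height_cm = "iii", cover_pct = "iv")
  out <- list()
  for (s in names(mono))
    for (attr in names(ids))
      out[[length(out) + 1L]] <- grab(mono[[s]], s, attr, ids[[attr]])
  if (!is.null(mixture)) {
    out[[length(out) + 1L]] <- grab(mixture, "community", "lai", "v")
    out[[length(out) + 1L]] <- grab(mixture, "community", "height_cm", "vi")
    for (s in names(mono)) {
      out[[length(out) + 1L]] <- grab(mixture, s, "agb_g_m2", "vii")
      out[[length(out) + 1L]] <- grab(mixture, s, "cover_pct", "viii")
    }
    for (s in names(mono)) {
      for (ry in list(c("agb_g_m2", "ix"), c("cover_pct", "x"))) {
        mx <- grab(mixture, s, ry[1], ry[2])
        mo <- grab(mono[[s]], s, ry[1], ry[2])
        if (is.null(mx) || is.null(mo)) next
        yrs <- intersect(mx$year, mo$year)
        if (!length(yrs)) next
        mx <- mx[match(yrs, mx$year), ]; mo <- mo[match(yrs, mo$year), ]
        if (any(mo$mean <= 0)) stop("zero monoculture value in relative yield")
        out[[length(out) + 1L]] <- data.frame(
          pattern_id = ry[2], subject = s, attribute = paste0("ry_", ry[1]),
          year = yrs, mean = mx$mean / mo$mean,
          min = mx$min / mo$mean, max = mx$max / mo$mean,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}
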