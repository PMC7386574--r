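## Daily climate drivers: a synthetic temperate seasonal generator and a CSV
## reader. Columns follow the package's climate contract:
##   date, tmean_C, par_mol_m2_d, daylength_h, precip_mm, pet_mm

#' Settings of the synthetic temperate climate generator
#'
#' Defaults emulate a Central European lowland climate: annual mean
#' temperature 8.5 degC with seasonal amplitude 9 degC peaking in mid July,
#' photosynthetically active radiation averaging 22 mol photons m^-2 d^-1
#' (amplitude 18), rainfall from a two-state Markov occurrence chain
#' (wet-after-dry 0.3, wet-after-wet 0.55) with exponential daily amounts of
#' mean 4.5 mm (roughly 660 mm yr^-1), and potential evapotranspiration
#' following the temperature sinusoid (mean 1.4, amplitude 1.4 mm d^-1).
#'
#' @param tmean_C annual mean temperature (degC).
#' @param tamp_C seasonal temperature amplitude (degC).
#' @param tnoise_sd_C day-to-day Gaussian temperature noise (degC).
#' @param par_mean,par_amp,par_noise_sd PAR sinusoid (mol photons m^-2 d^-1).
#' @param peak_doy julian day of the seasonal maximum.
#' @param p_wet_dry,p_wet_wet Markov rainfall occurrence probabilities.
#' @param rain_mean_mm mean wet-day rainfall (mm).
#' @param pet_mean_mm,pet_amp_mm PET sinusoid (mm d^-1).
#' @param latitude site latitude (deg N), for day length.
#' @return A named list of generator settings.
#' @export
climate_params <- function(tmean_C = 8.5, tamp_C = 9, tnoise_sd_C = 3,
                           par_mean = 22, par_amp = 18, par_noise_sd = 4,
                           peak_doy = 196,
                           p_wet_dry = 0.3, p_wet_wet = 0.55,
                           rain_mean_mm = 4.5,
                           pet_mean_mm = 1.4, pet_amp_mm = 1.4,
                           latitude = 51) {
  as.list(environment())
}

#' Day length from latitude by standard solar geometry
#'
#' Solar declination from the day of year, then the half-day angle
#' `acos(-tan(lat) tan(decl))`; clamped for polar day/night.
#'
#' @param doy day of year (1-366), vectorized.
#' @param latitude latitude in degrees (-90, 90).
#' @return Day length in hours.
#' @export
daylength_hours <- function(doy, latitude) {
  if (!is.finite(latitude) || abs(latitude) >= 90) stop("invalid latitude")
  decl <- 23.44 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  x <- -tan(latitude * pi / 180) * tan(decl)
  x <- pmin(1, pmax(-1, x))
  24 * acos(x) / pi
}

#' Generate a synthetic daily climate series
#'
#' Temperature and PAR follow sinusoids peaking in mid summer plus Gaussian
#' noise; rainfall occurrence is a two-state Markov chain with exponential
#' amounts; PET follows a non-negative sinusoid; day length comes from
#' latitude. The series is reproducible under a fixed seed.
#'
#' @param years number of years to generate (>= 1).
#' @param start_year first calendar year (series uses 365-day years; Feb 29 is
#'   skipped when dating).
#' @param params settings from [climate_params()].
#' @param seed optional integer seed.
#' @return A data frame with columns `date`, `tmean_C`, `par_mol_m2_d`,
#'   `daylength_h`, `precip_mm`, `pet_mm`.
#' @export
generate_synthetic_climate <- function(years, start_year = 2003,
                                       params = climate_params(), seed = NULL) {
  stopifnot(years >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- params
  n <- 365L * as.integer(years)
  doy <- rep(1:365, years)
  season <- cos(2 * pi * (doy - p$peak_doy) / 365)
  tmean <- p$tmean_C + p$tamp_C * season + rnorm(n, 0, p$tnoise_sd_C)
  par <- pmax(0, p$par_mean + p$par_amp * season + rnorm(n, 0, p$par_noise_sd))
  wet <- integer(n)
  u <- runif(n)
  state <- 0L
  for (i in seq_len(n)) {
    pr <- if (state == 1L) p$p_wet_wet else p$p_wet_dry
    state <- as.integer(u[i] < pr)
    wet[i] <- state
  }
  amounts <- -p$rain_mean_mm * log(runif(n))  # Exp(mean = rain_mean_mm)
  precip <- wet * amounts
  pet <- pmax(0, p$pet_mean_mm + p$pet_amp_mm * season)
  # calendar dates, skipping Feb 29 so every simulated year has 365 days
  dates <- as.Date(character(0))
  for (y in start_year + seq_len(years) - 1L) {
    d <- seq(as.Date(paste0(y, "-01-01")), as.Date(paste0(y, "-12-31")), by = "day")
    d <- d[format(d, "%m-%d") != "02-29"]
    dates <- c(dates, d)
  }
  data.frame(date = dates, tmean_C = tmean, par_mol_m2_d = par,
             daylength_h = daylength_hours(doy, p$latitude),
             precip_mm = precip, pet_mm = pet)
}

# day of year on the package's 365-day calendar (Feb 29 collapses onto
# Feb 28, later days shift down by one)
doy365 <- function(dates) {
  j <- as.integer(strftime(dates, "%j"))
  y <- as.integer(strftime(dates, "%Y"))
  leap <- (y %% 4 == 0 & (y %% 100 != 0 | y %% 400 == 0)) & j >= 60
  j[leap] <- j[leap] - 1L
  j
}

#' Read a daily climate series from CSV
#'
#' Expects columns `date` (ISO), `tmean_C`, `par_mol_m2_d`, `precip_mm`,
#' `pet_mm`; `daylength_h` is computed from `latitude` when absent. The series
#' must be gap-free and daily.
#'
#' @param file CSV path.
#' @param latitude latitude used when `daylength_h` is missing.
#' @return A climate data frame (see [generate_synthetic_climate()]).
#' @export
read_climate_csv <- function(file, latitude = 51) {
  x <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("date", "tmean_C", "par_mol_m2_d", "precip_mm", "pet_mm")
  missing <- setdiff(need, names(x))
  if (length(missing)) stop("missing driver: ", paste(missing, collapse = ", "))
  x$date <- as.Date(x$date)
  if (anyNA(x$date)) stop("missing driver: unparseable date")
  dd <- diff(as.integer(x$date))
  # a skipped Feb 29 is tolerated: the package works on 365-day years
  feb29 <- format(x$date[-length(x$date)], "%m-%d") == "02-28" & dd == 2L
  if (any(dd != 1L & !feb29)) stop("missing driver: date gap")
  if (any(x$par_mol_m2_d < 0) || any(x$precip_mm < 0))
    stop("invalid driver value")
  if (is.null(x$daylength_h))
    x$daylength_h <- daylength_hours(doy365(x$date), latitude)
  x[c("date", "tmean_C", "par_mol_m2_d", "daylength_h", "precip_mm", "pet_mm")]
}
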