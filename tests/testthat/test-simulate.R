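# The daily community loop: empty runs, determinism, mowing, censuses,
# annual aggregation, and equivalence of the compiled loop with the R-level
# building blocks on a deterministic single plant.

test_that("an empty system stays empty", {
  tr <- fixture_traits("F_pratensis")
  tr$N_seed_meta <- 1e-12   # essentially no seed rain
  cl <- fixture_climate(1)
  sim <- run_simulation(tr, cl, make_mowing_schedule(1, 2003), seed = 1)
  expect_true(all(sim$census$agb_g_m2 == 0))
  expect_true(all(sim$census$cover_pct == 0))
  expect_true(all(sim$daily$n_plants == 0))
})

test_that("the same seed gives bit-identical censuses", {
  tr <- fixture_traits("F_pratensis")
  cl <- fixture_climate(2)
  mow <- fixture_mowing(2)
  a <- run_simulation(tr, cl, mow, seed = 7)
  b <- run_simulation(tr, cl, mow, seed = 7)
  expect_identical(a$census, b$census)
  expect_identical(a$daily, b$daily)
  c <- run_simulation(tr, cl, mow, seed = 8)
  expect_false(identical(a$census, c$census))
})

test_that("mowing: below-blade plants untouched, proportional cut, conservation", {
  pl <- fixture_plants()
  short <- pl[1, ]  # 3 cm
  r <- apply_mowing(short, 10)
  expect_equal(r$plants, short)
  expect_equal(r$harvest, 0)

  tall <- pl[2, ]  # 30 cm, shoot 5 g
  r2 <- apply_mowing(tall, 10)
  expect_equal(r2$plants$height, 10)
  expect_equal(r2$plants$shoot_green, 4 / 3, tolerance = 1e-12)
  expect_equal(r2$plants$shoot_senescent, 1 / 3, tolerance = 1e-12)
  expect_equal(r2$harvest, 5 * 2 / 3, tolerance = 1e-12)
  expect_equal(r2$plants$width, tall$width)  # width unchanged

  # conservation and idempotence on a mixed table
  r3 <- apply_mowing(pl, 10)
  expect_equal(r3$harvest + sum(r3$plants$shoot_green +
                                  r3$plants$shoot_senescent),
               sum(pl$shoot_green + pl$shoot_senescent), tolerance = 1e-12)
  r4 <- apply_mowing(r3$plants, 10)
  expect_equal(r4$harvest, 0)
  expect_equal(r4$plants, r3$plants)
})

test_that("census sums pools, areas and heights per species", {
  tl <- fixture_traits_list()
  expect_true(all(census(empty_plants(), tl)[, c("agb_g_m2", "cover_pct",
                                                 "lai", "height_cm")] == 0))

  # one plant with 5000 cm2 of leaf area on the 10000 cm2 patch: LAI 0.5
  tr <- tl$F_pratensis
  one <- data.frame(species = "F_pratensis", age = 1, height = 25, width = 15,
                    shoot_green = 5000 / tr$SLA, shoot_senescent = 0.5,
                    root = 1, stringsAsFactors = FALSE)
  cen <- census(one, tl)
  f <- cen[cen$species == "F_pratensis", ]
  expect_equal(f$lai, 0.5)
  expect_equal(f$agb_g_m2, 5000 / tr$SLA + 0.5)  # per 1 m2
  expect_equal(f$cover_pct, 100 * (pi / 4) * 225 / 10000)
  expect_equal(f$height_cm, 25)
  comm <- cen[cen$species == "community", ]
  expect_equal(comm$lai, f$lai)
  # absent species rows are zero
  expect_equal(cen[cen$species == "P_pratensis", "agb_g_m2"], 0)
})

test_that("annual aggregation produces mean and intra-annual range", {
  cen <- data.frame(date = as.Date(c("2003-06-19", "2003-09-19",
                                     "2004-06-19", "2004-09-19")),
                    species = "community",
                    agb_g_m2 = c(100, 200, 150, 250),
                    cover_pct = c(50, 70, 60, 80),
                    lai = c(1, 2, 1.5, 2.5),
                    height_cm = c(10, 30, 20, 40),
                    stringsAsFactors = FALSE)
  agg <- annual_aggregate(cen)
  a03 <- agg[agg$attribute == "agb_g_m2" & agg$year == 2003, ]
  expect_equal(a03$mean, 150)
  expect_equal(a03$min, 100)
  expect_equal(a03$max, 200)
  expect_equal(a03$n_census, 2L)
  # single census in a year degenerates to that value
  agg1 <- annual_aggregate(cen[1, ])
  expect_true(all(agg1$mean == agg1$min & agg1$mean == agg1$max))
})

test_that("the ten patterns are assembled with their roman ids", {
  mk <- function(vals) data.frame(subject = rep(c("sp", "community"),
                                                each = 8),
                                  attribute = rep(c("agb_g_m2", "lai",
                                                    "height_cm", "cover_pct"),
                                                  times = 4),
                                  year = rep(rep(2003:2004, each = 4), 2),
                                  mean = vals, min = vals * 0.8,
                                  max = vals * 1.2, n_census = 2L,
                                  stringsAsFactors = FALSE)
  mono <- list(sp = mk(seq(1, 16)))
  mix <- mk(seq(2, 32, by = 2))
  ps <- build_pattern_set(mono, mix)
  expect_setequal(unique(ps$pattern_id),
                  c("i", "ii", "iii", "iv", "v", "vi", "vii", "viii",
                    "ix", "x"))
  # relative yields are mixture over monoculture of the same attribute
  ry <- ps[ps$pattern_id == "ix", ]
  mono_agb <- mono$sp[mono$sp$attribute == "agb_g_m2" &
                        mono$sp$subject == "sp", "mean"]
  mix_agb <- mix[mix$attribute == "agb_g_m2" & mix$subject == "sp", "mean"]
  expect_equal(ry$mean, mix_agb / mono_agb)
})

test_that("compiled loop reproduces the R building blocks on one plant", {
  # a deterministic setting: no seed rain (winter days), negligible mortality,
  # unlimited soil resources
  tr <- fixture_traits("F_pratensis")
  tr$m_seed <- 1e-15
  tr$m_basic <- 1e-15
  tl <- list(F_pratensis = tr)

  cl <- fixture_climate(1)[31:90, ]  # doy 31..90, before the seed window
  cfg <- sim_config(water_capacity = 1e6, mineral_N_init = 1e6,
                    n_deposition = 0)
  d0 <- dimensions_from_shoot_biomass(2.2, tr)
  init <- data.frame(species = "F_pratensis", age = 100,
                     height = d0[["height"]], width = d0[["width"]],
                     shoot_green = 2, shoot_senescent = 0.2, root = 1,
                     stringsAsFactors = FALSE)

  sim <- run_simulation(tl, cl, mowing = NULL, config = cfg,
                        init_plants = init, seed = 5)
  expect_equal(nrow(sim$final_plants), 1)

  # R-level composite of the same 60 days
  plant <- plant_state("F_pratensis", age = 100, height = d0[["height"]],
                       width = d0[["width"]], shoot_green = 2,
                       shoot_senescent = 0.2, root = 1)
  for (i in seq_len(nrow(cl))) {
    day <- cl[i, ]
    I0 <- if (day$par_mol_m2_d > 0 && day$daylength_h > 0)
      day$par_mol_m2_d * 1e6 / (day$daylength_h * 3600) else 0
    gpp <- plant_gross_photosynthesis(plant, I0, tr, day$daylength_h)
    lim <- limitation_factors(day, 1, 1)
    plant <- daily_carbon_update(plant, gpp, lim, tr)$plant
  }
  expect_equal(sim$final_plants$shoot_green, plant$shoot_green,
               tolerance = 1e-12)
  expect_equal(sim$final_plants$shoot_senescent, plant$shoot_senescent,
               tolerance = 1e-12)
  expect_equal(sim$final_plants$root, plant$root, tolerance = 1e-12)
  expect_equal(sim$final_plants$height, plant$height, tolerance = 1e-12)
  expect_equal(sim$final_plants$age, plant$age)
})

test_that("whole-system carbon closes daily on a stochastic 2-year run", {
  tr <- fixture_traits("F_pratensis")
  cl <- fixture_climate(2)
  sim <- run_simulation(tr, cl, fixture_mowing(2), seed = 13)
  d <- sim$daily
  resid <- d$living_mass -
    (d$cum_recruit + d$cum_gpp - d$cum_respiration - d$cum_litter -
       d$cum_harvest)
  expect_lt(max(abs(resid)) / max(d$living_mass), 1e-9)
  # crowding constraint after every day
  expect_lte(max(d$exclusive_area), sim$config$patch_area + 1e-6)
  # censuses are returned in date order
  expect_true(!is.unsorted(sim$census$date))
})

test_that("mowing dates outside the span are rejected", {
  tr <- fixture_traits("F_pratensis")
  cl <- fixture_climate(1)
  bad <- data.frame(date = as.Date("2010-06-20"), cut_height_cm = 10)
  expect_error(run_simulation(tr, cl, bad, seed = 1), "outside the simulated")
  expect_error(run_simulation(tr, cl, census_dates = as.Date("1999-01-01"),
                              seed = 1), "outside the simulated")
})

test_that("the shipped mowing schedule matches the twice-yearly generator", {
  f <- system.file("extdata", "mowing_biannual.csv", package = "grassim")
  sched <- read_mowing_csv(f)
  expect_equal(nrow(sched), 14)
  expect_true(all(sched$cut_height_cm == 10))
  gen <- make_mowing_schedule(7, 2002, establishment_year = TRUE)
  expect_equal(sched$date, gen$date)

  bad <- tempfile(fileext = ".csv")
  writeLines(c("date,cut_height_cm", "2003-06-20,0"), bad)
  expect_error(read_mowing_csv(bad), "positive")
  unlink(bad)
})
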