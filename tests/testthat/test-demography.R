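# Seed rain, emergence under the space budget, intrinsic mortality rates and
# crowding (self-thinning).

test_that("seed rain only falls inside the window, with Poisson counts", {
  tr <- fixture_traits("F_pratensis")  # t_meta = 136, N = 4013, germ = 0.3
  set.seed(41)
  expect_null(seed_rain_step(100, tr))
  expect_null(seed_rain_step(136 + 120, tr))

  co <- seed_rain_step(136, tr)
  expect_equal(co$species, "F_pratensis")
  expect_equal(co$emergence_day, 14)

  # Poisson mean: 4013 * 0.3 ~ 1204 germinating seeds per m2 and day
  counts <- replicate(200, seed_rain_step(150, tr)$count)
  expect_equal(mean(counts), 4013 * 0.3, tolerance = 0.02)

  # mixture seed rain for P. pratensis is the bracketed 1934
  trm <- fixture_traits("P_pratensis", context = "mixture")
  counts_m <- replicate(200, seed_rain_step(150, trm)$count)
  expect_equal(mean(counts_m), 1934 * 0.75, tolerance = 0.02)
})

test_that("emergence fills only the free space and discards the rest", {
  tl <- fixture_traits_list()
  due <- list(species = "F_pratensis", count = 10, emergence_day = 0)

  r <- emergence_step(list(), empty_plants(), tl)
  expect_equal(nrow(r$plants), 0)

  r <- emergence_step(list(due), empty_plants(), tl)
  expect_equal(nrow(r$plants), 10)
  expect_true(all(r$plants$age == 0))
  expect_equal(r$established, 10)

  # saturated patch: nothing establishes
  big <- data.frame(species = "F_pratensis", age = 500, height = 90,
                    width = 60, shoot_green = 100, shoot_senescent = 10,
                    root = 40, stringsAsFactors = FALSE)
  full <- big[rep(1, 4), ]  # 4 * pi/4 * 60^2 > 10000 cm2
  r2 <- emergence_step(list(due), full, tl)
  expect_equal(r2$established, 0)
  expect_equal(r2$discarded, 10)

  # a cohort not yet due stays untouched
  later <- list(species = "F_pratensis", count = 5, emergence_day = 3)
  r3 <- emergence_step(list(later), empty_plants(), tl)
  expect_equal(nrow(r3$plants), 0)
})

test_that("mortality uses the seedling rate below age_rep, compounded above", {
  tl <- fixture_traits_list()
  tr <- tl$F_pratensis  # age_rep = 0.2 yr = 73 d, m_seed = 0.038

  # compounded daily rate for m_basic = 0.02 / yr
  p_daily <- 1 - (1 - 0.02)^(1 / 365)
  expect_equal(p_daily, 5.53e-5, tolerance = 1e-3)

  # a 50-day-old seedling dies at m_seed: kill probability check by simulation
  seedling <- data.frame(species = "F_pratensis", age = 50, height = 3,
                         width = 2, shoot_green = 0.007, shoot_senescent = 0,
                         root = 0.003, stringsAsFactors = FALSE)
  many <- seedling[rep(1, 20000), ]
  set.seed(42)
  r <- mortality_step(many, tl)
  deaths <- 20000 - nrow(r$plants)
  # binomial 3 sigma around n * m_seed
  expect_lt(abs(deaths - 20000 * 0.038), 3 * sqrt(20000 * 0.038 * 0.962))

  # mature plants die at the compounded basic rate (simulate many)
  mature <- seedling; mature$age <- 400
  many_m <- mature[rep(1, 50000), ]
  set.seed(43)
  rm_ <- mortality_step(many_m, tl)
  deaths_m <- 50000 - nrow(rm_$plants)
  expect_lt(abs(deaths_m - 50000 * p_daily), 3 * sqrt(50000 * p_daily) + 3)

  # dead biomass arrives in litter
  expect_equal(r$litter[["above_mass"]], deaths * 0.007, tolerance = 1e-9)
  expect_equal(r$litter[["below_mass"]], deaths * 0.003, tolerance = 1e-9)
})

test_that("starved plants die deterministically", {
  tl <- fixture_traits_list()
  p <- data.frame(species = "F_pratensis", age = 400, height = 1, width = 1,
                  shoot_green = 1e-6, shoot_senescent = 0, root = 1e-6,
                  stringsAsFactors = FALSE)
  set.seed(44)
  r <- mortality_step(p, tl, starvation_floor = 1e-4)
  expect_equal(nrow(r$plants), 0)
})

test_that("crowding removes until the community fits, never below trigger", {
  tl <- fixture_traits_list()
  # two plants of 6000 cm2 exclusive each: exactly one is removed
  w6k <- sqrt(6000 / (pi / 4))
  two <- data.frame(species = "F_pratensis", age = 300, height = 50,
                    width = w6k, shoot_green = 10, shoot_senescent = 1,
                    root = 5, stringsAsFactors = FALSE)[rep(1, 2), ]
  set.seed(45)
  r <- crowding_step(two, tl)
  expect_equal(r$removed, 1)
  expect_equal(nrow(r$plants), 1)
  expect_equal(r$litter[["above_mass"]], 11)

  # under the limit: untouched
  ok <- two; ok$width <- sqrt(4000 / (pi / 4))
  r2 <- crowding_step(ok, tl)
  expect_equal(r2$removed, 0)

  # random communities always satisfy the constraint afterwards
  set.seed(46)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    pl <- data.frame(species = sample(names(tl), n, replace = TRUE),
                     age = runif(n, 0, 500), height = runif(n, 3, 60),
                     width = runif(n, 1, 40), shoot_green = rexp(n),
                     shoot_senescent = rexp(n, 5), root = rexp(n),
                     stringsAsFactors = FALSE)
    before <- sum(grassim:::plants_exclusive_area(pl, tl))
    r3 <- crowding_step(pl, tl)
    after <- sum(grassim:::plants_exclusive_area(r3$plants, tl))
    expect_lte(after, 10000)
    # mass leaving the living pool arrives in litter
    expect_equal(sum(pl$shoot_green + pl$shoot_senescent + pl$root) -
                   sum(r3$plants$shoot_green + r3$plants$shoot_senescent +
                         r3$plants$root),
                 r3$litter[["above_mass"]] + r3$litter[["below_mass"]],
                 tolerance = 1e-9)
  }

  # inverse-size bias prefers small victims (statistically)
  set.seed(47)
  mix <- data.frame(species = "F_pratensis", age = 300, height = 50,
                    width = c(rep(60, 3), rep(10, 30)),
                    shoot_green = c(rep(100, 3), rep(0.01, 30)),
                    shoot_senescent = 0, root = 1, stringsAsFactors = FALSE)
  r4 <- crowding_step(mix, tl, bias = "inverse_size")
  # the large plants dominate area; with inverse-size weighting many small
  # ones go first, so more than one plant is removed
  expect_gt(r4$removed, 1)
})
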