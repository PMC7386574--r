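# Shared fixtures: trait sets, short climate series and mowing schedules are
# built in code so every test constructs its inputs from the package itself.

fixture_traits <- function(species = "F_pratensis", context = "monoculture") {
  default_traits(species, context)
}

# deterministic-by-seed synthetic drivers, cached per (years, seed)
fixture_climate <- local({
  cache <- list()
  function(years = 3, seed = 101) {
    key <- paste(years, seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- generate_synthetic_climate(years, start_year = 2003,
                                                  seed = seed)
    cache[[key]]
  }
})

fixture_mowing <- function(years = 3) make_mowing_schedule(years, 2003)

# a small hand-made plant table spanning sizes and species
fixture_plants <- function() {
  data.frame(species = c("F_pratensis", "F_pratensis", "P_lanceolata"),
             age = c(10, 400, 200),
             height = c(3, 30, 20),
             width = c(2, 20, 33.3),
             shoot_green = c(0.006, 4, 5),
             shoot_senescent = c(0, 1, 1),
             root = c(0.003, 2, 0.5),
             stringsAsFactors = FALSE)
}

fixture_traits_list <- function() {
  list(F_pratensis = default_traits("F_pratensis"),
       P_pratensis = default_traits("P_pratensis"),
       P_lanceolata = default_traits("P_lanceolata"))
}
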