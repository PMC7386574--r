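## Species trait tables: validation, (de)serialization, and the mapping of the
## calibratable subset onto a bounded real vector for the optimizers.

.trait_fields <- c(
  "h_max", "hw", "f_s", "f_O", "SLA", "SRL", "rooting_depth_powerlaw", "sr",
  "N_seed_meta", "t_meta", "t_em", "germ_pct", "h_min", "age_rep",
  "LLS", "RLS", "m_seed", "m_basic", "life",
  "p_max", "alpha", "k", "m",
  "WUE", "CN_green", "CN_sen", "N_fix",
  "alloc_shoot", "r_m", "r_g"
)

# strictly positive scalars
.trait_positive <- c(
  "h_max", "hw", "f_s", "SLA", "SRL", "sr", "N_seed_meta", "t_em",
  "h_min", "age_rep", "LLS", "RLS", "m_seed", "p_max", "alpha", "k",
  "WUE", "CN_green", "CN_sen", "r_m"
)

# fractions / probabilities in [0, 1]
.trait_fraction <- c("germ_pct", "alloc_shoot", "r_g", "m", "m_basic")

#' Construct and validate a species trait set
#'
#' Bundles the 30 per-species parameters of the grassland model: plant
#' geometry (`h_max`, `hw`, `f_s`, `f_O`, `SLA`, `SRL`,
#' `rooting_depth_powerlaw`, `sr`), recruitment (`N_seed_meta`, `t_meta`,
#' `t_em`, `germ_pct`, `h_min`, `age_rep`), mortality (`LLS`, `RLS`,
#' `m_seed`, `m_basic`, `life`), photosynthesis (`p_max`, `alpha`, `k`, `m`),
#' resource competition (`WUE`, `CN_green`, `CN_sen`, `N_fix`) and growth
#' (`alloc_shoot`, `r_m`, `r_g`).
#'
#' Invariants enforced: rates, lengths and densities strictly positive;
#' probabilities and fractions in \[0, 1\]; the overlapping factor `f_O` in
#' (0, 1\]; `CN_sen >= CN_green` (senescent tissue is nitrogen-depleted);
#' the seedling starting height `h_min` (m) below `h_max` (cm) after unit
#' conversion.
#'
#' @param ... named trait values (see field list above). `species` names the
#'   set; `rooting_depth_powerlaw` is the ordered pair (r1, r2) of the
#'   rooting-depth power law.
#' @return An object of class `species_traits` (a validated named list).
#' @seealso [load_species_traits()], [default_traits()]
#' @export
species_traits <- function(...) {
  x <- list(...)
  if (length(x) == 1L && is.list(x[[1]]) && is.null(names(x)[1])) x <- x[[1]]
  validate_species_traits(x)
}

#' @rdname species_traits
#' @param x a named list of trait values.
#' @export
validate_species_traits <- function(x) {
  missing <- setdiff(.trait_fields, names(x))
  if (length(missing))
    stop("incomplete trait set: missing ", paste(missing, collapse = ", "))
  num_fields <- setdiff(.trait_fields, c("life", "N_fix", "rooting_depth_powerlaw"))
  for (f in num_fields) {
    v <- x[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("invalid trait value: ", f)
  }
  for (f in .trait_positive)
    if (x[[f]] <= 0) stop("invalid trait value: ", f)
  for (f in .trait_fraction)
    if (x[[f]] < 0 || x[[f]] > 1) stop("invalid trait value: ", f)
  if (x$f_O <= 0 || x$f_O > 1) stop("invalid trait value: f_O")
  rp <- x$rooting_depth_powerlaw
  if (!is.numeric(rp) || length(rp) != 2L || any(!is.finite(rp)) || rp[1] <= 0)
    stop("invalid trait value: rooting_depth_powerlaw")
  if (x$CN_sen < x$CN_green) stop("invalid trait value: CN_sen (< CN_green)")
  if (100 * x$h_min >= x$h_max) stop("invalid trait value: h_min (>= h_max)")
  if (!is.null(x[["N_seed_meta_mixture"]]) && x$N_seed_meta_mixture <= 0)
    stop("invalid trait value: N_seed_meta_mixture")
  if (is.null(x$species)) x$species <- "unnamed"
  x$N_fix <- isTRUE(x$N_fix) || identical(x$N_fix, "yes")
  class(x) <- "species_traits"
  x
}

#' Read a species trait set from a YAML file or record
#'
#' Trait files are YAML, one document per species, with field names matching
#' the trait symbols (see [species_traits()]). The optional field
#' `N_seed_meta_mixture` carries the seed rain used when the species grows in
#' a mixture rather than its monoculture.
#'
#' @param source path to a YAML file, or an already-parsed named list.
#' @return A validated `species_traits` object.
#' @export
load_species_traits <- function(source) {
  if (is.character(source) && length(source) == 1L) {
    if (!file.exists(source)) stop("no such trait file: ", source)
    source <- yaml::read_yaml(source)
  }
  if (!is.list(source)) stop("incomplete trait set: not a record")
  validate_species_traits(source)
}

#' Write a species trait set to YAML
#'
#' Round-trips losslessly through [load_species_traits()].
#'
#' @param traits a `species_traits` object.
#' @param file output path.
#' @export
write_species_traits <- function(traits, file) {
  stopifnot(inherits(traits, "species_traits"))
  x <- unclass(traits)
  x$N_fix <- if (isTRUE(x$N_fix)) "yes" else "no"
  yaml::write_yaml(x, file, precision = 15L)
  invisible(file)
}

#' Built-in parameter sets for the three study species
#'
#' Returns the shipped trait set for one of the two grasses
#' (*Festuca pratensis*, *Poa pratensis*) or the forb
#' (*Plantago lanceolata*). With `context = "mixture"` the mixture seed rain
#' replaces the monoculture value for species that carry one.
#'
#' @param species one of `"F_pratensis"`, `"P_pratensis"`, `"P_lanceolata"`.
#' @param context `"monoculture"` (default) or `"mixture"`.
#' @return A `species_traits` object.
#' @export
default_traits <- function(species = c("F_pratensis", "P_pratensis", "P_lanceolata"),
                           context = c("monoculture", "mixture")) {
  species <- match.arg(species)
  context <- match.arg(context)
  file <- switch(species,
    F_pratensis  = "festuca_pratensis.yaml",
    P_pratensis  = "poa_pratensis.yaml",
    P_lanceolata = "plantago_lanceolata.yaml")
  tr <- load_species_traits(
    system.file("extdata", "traits", file, package = "grassim", mustWork = TRUE))
  if (context == "mixture" && !is.null(tr[["N_seed_meta_mixture"]]))
    tr$N_seed_meta <- tr$N_seed_meta_mixture
  tr
}

#' Export one or more trait sets as a CSV table
#'
#' One row per species, one column per parameter; the rooting-depth pair is
#' split into `r1` and `r2`.
#'
#' @param traits_list a list of `species_traits` objects.
#' @param file output path, or `NULL` to return the data frame only.
#' @return The exported data frame, invisibly if written.
#' @export
export_traits_csv <- function(traits_list, file = NULL) {
  if (inherits(traits_list, "species_traits")) traits_list <- list(traits_list)
  rows <- lapply(traits_list, function(tr) {
    x <- unclass(tr)
    x$r1 <- x$rooting_depth_powerlaw[1]
    x$r2 <- x$rooting_depth_powerlaw[2]
    x$rooting_depth_powerlaw <- NULL
    x$N_fix <- if (isTRUE(x$N_fix)) "yes" else "no"
    as.data.frame(x[!vapply(x, is.null, logical(1))], stringsAsFactors = FALSE)
  })
  cols <- Reduce(union, lapply(rows, names))
  rows <- lapply(rows, function(r) { r[setdiff(cols, names(r))] <- NA; r[cols] })
  out <- do.call(rbind, rows)
  if (!is.null(file)) { write.csv(out, file, row.names = FALSE); return(invisible(out)) }
  out
}

#' @export
print.species_traits <- function(x, ...) {
  cat("<species_traits> ", x$species, "\n", sep = "")
  cat("  geometry: h_max=", x$h_max, " cm, hw=", x$hw, ", f_s=", x$f_s,
      ", f_O=", x$f_O, ", SLA=", x$SLA, "\n", sep = "")
  cat("  photosynthesis: p_max=", x$p_max, ", alpha=", x$alpha,
      ", k=", x$k, ", m=", x$m, "\n", sep = "")
  cat("  recruitment: N_seed_meta=", x$N_seed_meta, "/m2/d from day ",
      x$t_meta, ", germ=", x$germ_pct, "\n", sep = "")
  invisible(x)
}

## ---- trait bounds and the free-parameter vector ---------------------------

# The 16 inversely parameterized traits (the rooting-depth pair, SRL aside,
# which the simplified soil does not consume, is still calibratable as a
# stored trait).
.calibratable_traits <- c(
  "hw", "f_s", "SLA", "SRL", "N_seed_meta", "age_rep", "LLS", "RLS",
  "m_seed", "p_max", "alpha", "k", "WUE", "CN_green", "CN_sen", "alloc_shoot"
)

#' Bounds on the calibratable trait subset
#'
#' A `trait_bounds` object marks which traits the optimizers may move and the
#' box each one lives in. Fixed-from-literature and estimated traits are never
#' touched during calibration.
#'
#' @param lower,upper named numeric vectors with identical names (the
#'   calibratable traits); `lower < upper` element-wise.
#' @return An object of class `trait_bounds`.
#' @export
trait_bounds <- function(lower, upper) {
  stopifnot(is.numeric(lower), is.numeric(upper),
            !is.null(names(lower)), identical(names(lower), names(upper)))
  if (any(lower >= upper)) stop("trait bounds: lower >= upper for ",
                                paste(names(lower)[lower >= upper], collapse = ", "))
  structure(list(lower = lower, upper = upper, free = names(lower)),
            class = "trait_bounds")
}

#' Default bounds for the 16 inversely parameterized traits
#'
#' Broad, biologically plausible boxes spanning the shipped values of all
#' three species. With `include_overlap = TRUE` the overlapping factor `f_O`
#' is added as a 17th free trait (it is calibrated for the forb only).
#'
#' @param free optional character vector restricting the bounds to a subset of
#'   the calibratable traits.
#' @param include_overlap add `f_O` to the free set.
#' @return A `trait_bounds` object.
#' @export
default_trait_bounds <- function(free = NULL, include_overlap = FALSE) {
  lower <- c(hw = 0.2, f_s = 1e-4, SLA = 50, SRL = 5e3, N_seed_meta = 100,
             age_rep = 0.01, LLS = 30, RLS = 60, m_seed = 0.005,
             p_max = 5, alpha = 0.01, k = 0.1, WUE = 1,
             CN_green = 10, CN_sen = 35, alloc_shoot = 0.1)
  upper <- c(hw = 3, f_s = 3e-3, SLA = 400, SRL = 2e5, N_seed_meta = 8000,
             age_rep = 1, LLS = 400, RLS = 800, m_seed = 0.15,
             p_max = 60, alpha = 0.15, k = 1.2, WUE = 12,
             CN_green = 35, CN_sen = 80, alloc_shoot = 0.9)
  if (include_overlap) { lower <- c(lower, f_O = 0.3); upper <- c(upper, f_O = 1) }
  if (!is.null(free)) {
    bad <- setdiff(free, names(lower))
    if (length(bad)) stop("not a calibratable trait: ", paste(bad, collapse = ", "))
    lower <- lower[free]; upper <- upper[free]
  }
  trait_bounds(lower, upper)
}

#' Map a trait set to/from the optimizer's bounded real vector
#'
#' `encode_free_parameters` extracts the free traits named by `bounds` into a
#' named numeric vector; `decode_free_parameters` writes such a vector back
#' into a trait set, leaving all fixed traits untouched. The two are mutual
#' inverses for any in-bounds vector.
#'
#' @param traits a `species_traits` object.
#' @param bounds a `trait_bounds` object.
#' @return `encode_free_parameters`: a named numeric vector of length
#'   `length(bounds$free)`.
#' @export
encode_free_parameters <- function(traits, bounds) {
  stopifnot(inherits(traits, "species_traits"), inherits(bounds, "trait_bounds"))
  x <- vapply(bounds$free, function(f) as.numeric(traits[[f]]), numeric(1))
  names(x) <- bounds$free
  x
}

#' @rdname encode_free_parameters
#' @param x a named numeric vector as produced by `encode_free_parameters`.
#' @export
decode_free_parameters <- function(x, traits, bounds) {
  stopifnot(inherits(traits, "species_traits"), inherits(bounds, "trait_bounds"))
  if (length(x) != length(bounds$free))
    stop("free-parameter vector length ", length(x),
         " does not match bounds (", length(bounds$free), ")")
  if (any(x < bounds$lower - 1e-12) || any(x > bounds$upper + 1e-12))
    stop("free-parameter component out of bounds: ",
         paste(bounds$free[x < bounds$lower | x > bounds$upper], collapse = ", "))
  for (i in seq_along(bounds$free)) traits[[bounds$free[i]]] <- unname(x[i])
  validate_species_traits(unclass(traits))
}
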