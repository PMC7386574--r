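## Plant geometry: biomass <-> encasing-cylinder dimensions, ground and leaf
## areas, rooting depth, seedling creation.
##
## The shoot (green + senescent) is assumed to fill the plant's encasing
## cylinder at the effective tissue density f_s (g cm^-3):
##     B = f_s * (pi/4) * w^2 * h,   with h = hw * w on the isometric path.
## Above the species maximum height the cylinder widens at fixed h = h_max.

#' Create a single plant state
#'
#' A plant is described by its species, age (days), the encasing cylinder
#' (height and width, cm), the biomass pools (green shoot, senescent shoot and
#' root, g organic dry matter) and a living flag.
#'
#' @param species_id species name (must match a trait set).
#' @param age age in days.
#' @param height,width cylinder dimensions in cm.
#' @param shoot_green,shoot_senescent,root biomass pools in g ODM.
#' @param alive logical.
#' @return An object of class `plant_state`.
#' @export
plant_state <- function(species_id, age = 0, height = 0, width = 0,
                        shoot_green = 0, shoot_senescent = 0, root = 0,
                        alive = TRUE) {
  stopifnot(age >= 0, height >= 0, width >= 0,
            shoot_green >= 0, shoot_senescent >= 0, root >= 0)
  structure(list(species_id = species_id, age = age, height = height,
                 width = width, shoot_green = shoot_green,
                 shoot_senescent = shoot_senescent, root = root,
                 alive = alive),
            class = "plant_state")
}

#' Cylinder dimensions from shoot biomass (isometric growth path)
#'
#' Inverts the encasing-cylinder relation `B = f_s * (pi/4) * w^2 * h` under
#' the isometric constraint `h = hw * w`. Above the species cap the height is
#' fixed at `h_max` and additional biomass widens the plant, so the mapping
#' stays single-valued and mass-conserving.
#'
#' @param shoot_total total shoot biomass (green + senescent), g ODM.
#' @param traits a `species_traits` object.
#' @return Numeric vector `c(height, width)` in cm.
#' @export
dimensions_from_shoot_biomass <- function(shoot_total, traits) {
  stopifnot(length(shoot_total) == 1L)
  if (shoot_total < 0) stop("negative biomass")
  w <- (4 * shoot_total / (pi * traits$f_s * traits$hw))^(1 / 3)
  h <- traits$hw * w
  if (h > traits$h_max) {
    h <- traits$h_max
    w <- sqrt(4 * shoot_total / (pi * traits$f_s * traits$h_max))
  }
  c(height = h, width = w)
}

#' Shoot biomass held by a cylinder
#'
#' The forward relation `B = f_s * (pi/4) * w^2 * h`; inverse of
#' [dimensions_from_shoot_biomass()] below the height cap.
#'
#' @param height,width cylinder dimensions, cm.
#' @inheritParams dimensions_from_shoot_biomass
#' @return Shoot biomass, g ODM.
#' @export
shoot_biomass_from_dimensions <- function(height, width, traits) {
  traits$f_s * (pi / 4) * width^2 * height
}

#' Ground and leaf areas of a plant
#'
#' `cover_area` is the cylinder footprint `(pi/4) w^2`; `exclusive_area`
#' is the footprint scaled by the overlapping factor `f_O` (the space the
#' plant claims against the crowding limit); `leaf_area` is `SLA` times the
#' green shoot pool only.
#'
#' @param plant a `plant_state`.
#' @inheritParams dimensions_from_shoot_biomass
#' @return Named numeric vector `c(cover_area, exclusive_area, leaf_area)`
#'   in cm^2.
#' @export
plant_areas <- function(plant, traits) {
  cover <- (pi / 4) * plant$width^2
  c(cover_area = cover,
    exclusive_area = traits$f_O * cover,
    leaf_area = traits$SLA * plant$shoot_green)
}

#' Rooting depth from root biomass
#'
#' Power law `depth = r1 * root^r2` with the species pair
#' `rooting_depth_powerlaw = (r1, r2)`.
#'
#' @param root root biomass, g ODM (vectorized).
#' @inheritParams dimensions_from_shoot_biomass
#' @return Depth in cm.
#' @export
rooting_depth <- function(root, traits) {
  stopifnot(all(root >= 0))
  r <- traits$rooting_depth_powerlaw
  r[1] * root^r[2]
}

#' Create a newly emerged seedling
#'
#' A seedling starts at the species' initial height `h_min` (converted m to
#' cm) on the isometric path: width `h/hw`, green shoot filling the cylinder,
#' no senescent shoot, and root set by the shoot-root ratio `sr`.
#'
#' @inheritParams dimensions_from_shoot_biomass
#' @param day julian day of emergence (recorded only).
#' @return A `plant_state` of age 0.
#' @export
make_seedling <- function(traits, day = 0) {
  h <- 100 * traits$h_min
  w <- h / traits$hw
  sg <- shoot_biomass_from_dimensions(h, w, traits)
  plant_state(species_id = traits$species, age = 0, height = h, width = w,
              shoot_green = sg, shoot_senescent = 0, root = sg / traits$sr)
}

#' Update cylinder dimensions after a biomass change
#'
#' On the growth path the isometric relation of
#' [dimensions_from_shoot_biomass()] applies. After mowing, a plant's height
#' lies below `hw * width`; it then keeps its width and regrows in height only
#' (height = B / (f_s (pi/4) w^2)) until the isometric height is reached
#' again. The cylinder always holds exactly the current shoot biomass.
#'
#' @param plant a `plant_state` whose pools have just changed.
#' @inheritParams dimensions_from_shoot_biomass
#' @return The plant with updated `height` and `width`.
#' @export
update_dimensions <- function(plant, traits) {
  B <- plant$shoot_green + plant$shoot_senescent
  if (B <= 0) { plant$height <- 0; plant$width <- 0; return(plant) }
  w <- plant$width
  h_need <- if (w > 0) B / (traits$f_s * (pi / 4) * w^2) else Inf
  if (h_need >= traits$hw * w) {          # isometric (or first) growth
    d <- dimensions_from_shoot_biomass(B, traits)
    plant$height <- d[["height"]]; plant$width <- d[["width"]]
  } else if (h_need > traits$h_max) {     # wide plant pinned at the cap
    plant$height <- traits$h_max
    plant$width <- sqrt(4 * B / (pi * traits$f_s * traits$h_max))
  } else {                                # post-mowing height regrowth
    plant$height <- h_need
  }
  plant
}
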