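#' Nano-well lattice geometry
#'
#' A patterned flow cell carries hexagonally packed nano-wells. The geometry
#' of one surface is fully described by the centre-to-centre pitch and the
#' well opening diameter, both in nanometres.
#'
#' @param pitch Centre-to-centre well spacing in nm. Must be positive.
#' @param diameter Well opening diameter in nm. Must satisfy
#'   `0 < diameter < 2 * pitch`.
#' @return An object of class `well_geometry`.
#' @examples
#' s4 <- well_geometry(pitch = 625, diameter = 300)
#' packing_density(s4)
#' @export
well_geometry <- function(pitch, diameter) {
  if (!is.numeric(pitch) || length(pitch) != 1L || !is.finite(pitch) || pitch <= 0)
    stop("invalid geometry: pitch must be a positive finite number")
  if (!is.numeric(diameter) || length(diameter) != 1L || !is.finite(diameter) ||
      diameter <= 0 || diameter >= 2 * pitch)
    stop("invalid geometry: diameter must satisfy 0 < diameter < 2*pitch")
  structure(list(pitch = pitch, diameter = diameter), class = "well_geometry")
}

#' @export
print.well_geometry <- function(x, ...) {
  cat(sprintf("well_geometry: pitch %g nm, diameter %g nm\n", x$pitch, x$diameter))
  invisible(x)
}

#' Area of one hexagonal lattice unit cell
#'
#' In a hexagonal packing each lattice site owns an area of
#' `sqrt(3)/2 * pitch^2` (the rhombic unit cell).
#'
#' @param geom A [well_geometry()].
#' @return Area per lattice site in nm^2.
#' @export
hex_unit_cell_area <- function(geom) {
  stopifnot(inherits(geom, "well_geometry"))
  sqrt(3) / 2 * geom$pitch^2
}

#' Nano-well packing density
#'
#' Number of lattice sites (capture spots) per 100 square micrometres,
#' i.e. `1e8 nm^2 / hex_unit_cell_area(geom)`.
#'
#' @inheritParams hex_unit_cell_area
#' @return Wells per 100 um^2.
#' @export
packing_density <- function(geom) {
  1e8 / hex_unit_cell_area(geom)
}

#' Dead space per lattice site
#'
#' The area of one unit cell not occupied by the well opening:
#' `hex_unit_cell_area - pi * (diameter/2)^2`. Defined per lattice site;
#' the well circle must fit within the unit cell area.
#'
#' @inheritParams hex_unit_cell_area
#' @return Dead area in nm^2 per lattice site.
#' @export
dead_space_per_well <- function(geom) {
  cell <- hex_unit_cell_area(geom)
  circ <- pi * (geom$diameter / 2)^2
  if (circ - cell > 1e-9 * cell)
    stop("invalid geometry: well area exceeds unit-cell area")
  max(cell - circ, 0)
}

#' Dead-space reduction ratio between two geometries
#'
#' Ratio `dead_space_per_well(a) / dead_space_per_well(b)`; used to compare
#' a coarser surface (a) against a denser one (b).
#'
#' @param a,b [well_geometry()] objects (numerator and denominator).
#' @return Dimensionless ratio.
#' @examples
#' dead_space_reduction(well_geometry(625, 300), well_geometry(399, 280))
#' @export
dead_space_reduction <- function(a, b) {
  db <- dead_space_per_well(b)
  if (db == 0)
    stop("dead space of denominator geometry is zero; ratio undefined")
  dead_space_per_well(a) / db
}

#' Chip yield from a dicing plan
#'
#' A flow cell diced into `sections` two-layer pieces yields
#' `sections * layers_per_section` single-surface chips (both inner glass
#' surfaces are functional).
#'
#' @param sections Number of diced pieces (>= 0).
#' @param layers_per_section Functional surfaces per piece, 1 or 2.
#' @return Count of single-surface chips.
#' @examples
#' chip_yield(sections = 56, layers_per_section = 2)
#' @export
chip_yield <- function(sections, layers_per_section = 2L) {
  if (!is.numeric(sections) || length(sections) != 1L || sections < 0 ||
      sections != round(sections))
    stop("sections must be a non-negative integer")
  if (!layers_per_section %in% c(1L, 2L))
    stop("layers_per_section must be 1 or 2")
  as.integer(sections) * as.integer(layers_per_section)
}
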