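#' Cortical column geometry
#'
#' Describes the layered cylindrical volume of the cortical column. Depth (`y`)
#' increases downward from the pia, with `y = 0` at the top of L1. The default
#' dimensions are a 2,082 um tall cylinder of radius 210 um with layer
#' thicknesses L1 165, L2/3 502, L4 190, L5 525 and L6 700 um.
#'
#' @param height Column height in um.
#' @param radius Column radius in um.
#' @param layer_thicknesses Named numeric vector of layer thicknesses (um),
#'   ordered from the pia downward. Must sum to `height`.
#' @return A `tc_column_geometry` object.
#' @export
#' @examples
#' geo <- column_geometry()
#' layer_bounds(geo)
column_geometry <- function(height = 2082, radius = 210,
                            layer_thicknesses = c(L1 = 165, L23 = 502, L4 = 190,
                                                  L5 = 525, L6 = 700)) {
  if (any(layer_thicknesses <= 0)) abort("layer thicknesses must be positive")
  if (radius <= 0) abort("radius must be positive")
  if (abs(sum(layer_thicknesses) - height) > 1e-9)
    abort(sprintf("layer thicknesses sum to %g but height is %g",
                  sum(layer_thicknesses), height))
  structure(list(height = height, radius = radius,
                 layer_thicknesses = layer_thicknesses),
            class = "tc_column_geometry")
}

#' Layer depth intervals of a cortical column
#'
#' Cumulative half-open depth intervals `[y_top, y_bottom)` per layer, covering
#' `[0, height)` from the pia downward.
#'
#' @param geometry A [column_geometry()] object.
#' @return A tibble with columns `layer`, `y_top`, `y_bottom`.
#' @export
layer_bounds <- function(geometry) {
  th <- geometry$layer_thicknesses
  bottoms <- cumsum(th)
  tibble(layer = names(th),
         y_top = unname(c(0, bottoms[-length(bottoms)])),
         y_bottom = unname(bottoms))
}

#' Thalamic stacked-box geometry
#'
#' Six populations in vertically stacked boxes sharing a square footprint in
#' the XZ plane. Stacking order, from top to bottom, is the three reticular
#' (RTN) sectors followed by the relay nuclei. Depths are expressed in the same
#' downward-increasing `y` frame as the cortical column; the stack sits below
#' the column at a configurable vertical separation (the separation affects
#' visualization only, since wiring rules use XZ distance and box-aligned
#' depth offsets).
#'
#' @param xz_side Side (um) of the square footprint in the XZ plane.
#' @param sector_heights Named vector of box heights (um), in stacking order.
#' @param y_offset Depth (um) of the top of the thalamic stack.
#' @return A `tc_thalamic_geometry` object.
#' @export
thalamic_geometry <- function(xz_side = 420,
                              sector_heights = c(RTNo = 78, RTNm = 78, RTNi = 156,
                                                 VPL = 156, VPM = 156, POm = 312),
                              y_offset = 2582) {
  if (any(sector_heights <= 0)) abort("sector heights must be positive")
  bottoms <- cumsum(sector_heights) + y_offset
  boxes <- tibble(population = names(sector_heights),
                  y_top = c(y_offset, bottoms[-length(bottoms)]),
                  y_bottom = unname(bottoms))
  structure(list(xz_side = xz_side, sector_heights = sector_heights,
                 y_offset = y_offset, boxes = boxes),
            class = "tc_thalamic_geometry")
}

# area-uniform sampling of a disc by inverse CDF on the radius
sample_disc <- function(n, radius) {
  r <- radius * sqrt(runif(n))
  theta <- runif(n, 0, 2 * pi)
  tibble(x = r * cos(theta), z = r * sin(theta))
}

#' Place cortical cells in the layered cylinder
#'
#' Each cell is placed uniformly at random within its layer's disc slice:
#' uniform over the disc area (radius sampled by inverse CDF as `R*sqrt(u)`)
#' and uniform in depth within the layer.
#'
#' @param counts Tibble with columns `me_type`, `layer`, `m_type`, `e_type`,
#'   `excitatory`, `count` (see [gen_cell_counts()]).
#' @param geometry A [column_geometry()] object.
#' @param seed Integer seed; placement is reproducible given the seed.
#' @return A tibble of cell instances: `id`, `population`, `me_type`, `m_type`,
#'   `e_type`, `layer`, `x`, `y`, `z`, `excitatory`.
#' @export
place_cortical_cells <- function(counts, geometry = column_geometry(), seed = 1) {
  if (any(counts$count < 0)) abort("counts must be >= 0")
  lb <- layer_bounds(geometry)
  unknown <- setdiff(unique(counts$layer), lb$layer)
  if (length(unknown) > 0)
    abort(paste0("unknown layer name(s): ", paste(unknown, collapse = ", ")))
  counts <- filter(counts, .data$count > 0)
  if (nrow(counts) == 0) return(empty_cells())
  with_seed(seed, {
    cells <- purrr::pmap(counts, function(me_type, layer, m_type, e_type,
                                          excitatory, count, ...) {
      b <- lb[lb$layer == layer, ]
      xy <- sample_disc(count, geometry$radius)
      tibble(population = me_type, me_type = me_type, m_type = m_type,
             e_type = e_type, layer = layer,
             x = xy$x, y = runif(count, b$y_top, b$y_bottom), z = xy$z,
             excitatory = excitatory)
    })
    cells <- bind_rows(cells)
    cells$id <- seq_len(nrow(cells))
    select(cells, "id", dplyr::everything())
  })
}

#' Place thalamic cells in stacked boxes
#'
#' Cells are placed uniformly within each population's box. The POm population
#' is placed at reduced density (default 50%), reflecting the proportion of
#' functionally isolated M1-projecting cells that do not participate in the
#' modeled circuit.
#'
#' @param counts Tibble with columns `population`, `excitatory`,
#'   `nominal_count` (see [thalamic_cell_counts()]).
#' @param geometry A [thalamic_geometry()] object.
#' @param density_scaling Named vector of density multipliers in (0, 1];
#'   populations not named get 1.
#' @param seed Integer seed.
#' @param id_offset First cell id minus one (use to stack onto cortical ids).
#' @return A tibble of cell instances with the same columns as
#'   [place_cortical_cells()].
#' @export
place_thalamic_cells <- function(counts, geometry = thalamic_geometry(),
                                 density_scaling = c(POm = 0.5), seed = 1,
                                 id_offset = 0L) {
  if (any(density_scaling <= 0 | density_scaling > 1))
    abort("density scaling must be in (0, 1]")
  unknown <- setdiff(counts$population, geometry$boxes$population)
  if (length(unknown) > 0)
    abort(paste0("unknown thalamic population(s): ", paste(unknown, collapse = ", ")))
  half <- geometry$xz_side / 2
  with_seed(seed, {
    cells <- purrr::pmap(counts, function(population, excitatory, nominal_count, ...) {
      scal <- if (population %in% names(density_scaling))
        density_scaling[[population]] else 1
      nn <- as.integer(round(nominal_count * scal))
      if (nn == 0) return(NULL)
      b <- geometry$boxes[geometry$boxes$population == population, ]
      tibble(population = population, me_type = population, m_type = population,
             e_type = if (excitatory) "relay" else "reticular",
             layer = population,
             x = runif(nn, -half, half),
             y = runif(nn, b$y_top, b$y_bottom),
             z = runif(nn, -half, half),
             excitatory = excitatory)
    })
    cells <- bind_rows(cells)
    if (nrow(cells) == 0) return(empty_cells())
    cells$id <- seq_len(nrow(cells)) + as.integer(id_offset)
    select(cells, "id", dplyr::everything())
  })
}

empty_cells <- function() {
  tibble(id = integer(), population = character(), me_type = character(),
         m_type = character(), e_type = character(), layer = character(),
         x = numeric(), y = numeric(), z = numeric(), excitatory = logical())
}

#' Pairwise horizontal (XZ-plane) distance
#'
#' All wiring rules operate on the 2D somatic distance in the horizontal plane.
#'
#' @param a,b Tibbles of cells with `x` and `z` columns.
#' @return A `nrow(a) x nrow(b)` matrix of distances in um.
#' @export
xz_distance <- function(a, b) {
  dx <- outer(a$x, b$x, "-")
  dz <- outer(a$z, b$z, "-")
  sqrt(dx^2 + dz^2)
}

#' Export placements as tabular text
#'
#' @param cells Placement tibble.
#' @param path Output file path (TSV).
#' @return `path`, invisibly.
#' @export
write_placements <- function(cells, path) {
  utils::write.table(cells[, c("id", "population", "x", "y", "z")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
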