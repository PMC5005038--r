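# Hexagonal building layout: 18 buildings on a triangular lattice, the source
# of all direction geometry downstream.

#' Build the hexagonal city layout
#'
#' Places 18 buildings at the vertices of equilateral triangles arranged in a
#' hexagon of lattice side 2 (centre point excluded): 6 inner buildings at unit
#' radius on the main axes (0, 60, ..., 300 degrees), 6 outer buildings at
#' radius 2 on the same axes, and 6 outer buildings at radius `sqrt(3)` on the
#' 30-degree-offset axes. The 6 inner buildings serve as start locations for
#' the direction-imagination task; all start-to-target vectors used for
#' sampling then fall on a 30-degree direction grid.
#'
#' Angles are measured counter-clockwise from the +x axis; "north" is the +y
#' axis, so the cardinal directions are 0, 90, 180 and 270 degrees in layout
#' coordinates.
#'
#' @param scale Lattice-unit-to-meter factor (default 1; all downstream
#'   contrasts are invariant to it after distance standardization).
#' @param ns_street_x x-coordinate (in lattice units) of the designated
#'   north-south street column; trials running along this column with both
#'   endpoints on it are flagged for the street-control analysis.
#' @return An object of class `city_layout`: a list with a `buildings` tibble
#'   (`id`, `label`, `x`, `y`, `ring`, `radius`, `angle_deg`), the `scale`, and
#'   the street column.
#' @examples
#' layout <- build_city_layout()
#' nrow(layout$buildings) # 18
#' @export
build_city_layout <- function(scale = 1, ns_street_x = 0.5) {
  stopifnot_scalar_number(scale, "scale", min = .Machine$double.eps)
  k <- 0:5
  inner <- tibble(
    ring = "inner", radius = 1, angle_deg = 60 * k,
    x = cos(pi * k / 3), y = sin(pi * k / 3)
  )
  outer_far <- tibble(
    ring = "outer", radius = 2, angle_deg = 60 * k,
    x = 2 * cos(pi * k / 3), y = 2 * sin(pi * k / 3)
  )
  outer_mid <- tibble(
    ring = "outer", radius = sqrt(3), angle_deg = 30 + 60 * k,
    x = sqrt(3) * cos(pi / 6 + pi * k / 3),
    y = sqrt(3) * sin(pi / 6 + pi * k / 3)
  )
  buildings <- bind_rows(inner, outer_far, outer_mid)
  buildings <- mutate(buildings,
    id = dplyr::row_number(),
    label = sprintf("B%02d", .data$id)
  )
  buildings <- select(buildings, "id", "label", "x", "y", "ring", "radius", "angle_deg")
  structure(
    list(buildings = buildings, scale = scale, ns_street_x = ns_street_x),
    class = "city_layout"
  )
}

#' @export
print.city_layout <- function(x, ...) {
  cat("<city_layout> 18 buildings (6 inner starts, 12 outer), scale =",
      x$scale, "\n")
  print(x$buildings, n = 6)
  invisible(x)
}

validate_layout <- function(layout) {
  if (!inherits(layout, "city_layout")) {
    abort("`layout` must be a `city_layout` (see build_city_layout()).")
  }
  b <- layout$buildings
  if (nrow(b) != 18L || sum(b$ring == "inner") != 6L || sum(b$ring == "outer") != 12L) {
    abort("structural error: layout must have 18 buildings, 6 inner and 12 outer.")
  }
  invisible(layout)
}

# 18 x 18 inter-building distance matrix in layout units (times scale).
building_distances <- function(layout) {
  b <- layout$buildings
  as.matrix(stats::dist(cbind(b$x, b$y))) * layout$scale
}

#' Enumerate direction-sampling building combinations
#'
#' For each inner (start) building, finds every other building whose
#' start-to-target vector lies exactly on the 30-degree direction grid, and
#' retains one combination per distinct direction. When both an inner and an
#' outer building lie on the same direction from a start, the outer target is
#' selected; this is the unique rule under which inner-target trials never
#' occur in the 30-mod-60 condition. Each start yields 10 of the 12
#' directions: all 6 main-axis directions (multiples of 60) plus 4 of the 6
#' offset directions, for 60 combinations in total.
#'
#' @param layout A `city_layout`.
#' @return A tibble with one row per combination: `start_id`, `target_id`,
#'   `direction_deg`, `distance`, `target_ring`, `main_axis`.
#' @export
enumerate_combinations <- function(layout) {
  validate_layout(layout)
  b <- layout$buildings
  starts <- b$id[b$ring == "inner"]
  grid <- tidyr::expand_grid(start_id = starts, target_id = b$id)
  grid <- filter(grid, .data$start_id != .data$target_id)
  sx <- b$x[grid$start_id]; sy <- b$y[grid$start_id]
  tx <- b$x[grid$target_id]; ty <- b$y[grid$target_id]
  ang <- wrap_deg(atan2(ty - sy, tx - sx) * 180 / pi)
  grid <- mutate(grid,
    direction_deg = snap_to_grid(ang),
    distance = sqrt((tx - sx)^2 + (ty - sy)^2) * layout$scale,
    target_ring = b$ring[.data$target_id]
  )
  grid <- filter(grid, !is.na(.data$direction_deg))
  # one combination per (start, direction): prefer the outer-ring target,
  # then the farther one
  combos <- grid |>
    arrange(.data$start_id, .data$direction_deg,
            .data$target_ring != "outer", dplyr::desc(.data$distance)) |>
    group_by(.data$start_id, .data$direction_deg) |>
    dplyr::slice(1L) |>
    ungroup() |>
    mutate(main_axis = .data$direction_deg %% 60 == 0) |>
    arrange(.data$start_id, .data$direction_deg)
  if (nrow(combos) != 60L) {
    abort("structural error: expected 60 combinations from a valid layout.")
  }
  combos
}

#' Randomly exclude oversampled main-axis combinations
#'
#' The 60 combinations oversample the six main-axis directions (available from
#' all six starts versus four starts for the offset directions). Exactly two
#' combinations are removed for each main-axis direction, under the constraint
#' that exactly two combinations are removed per start location, leaving 48
#' combinations that sample every direction exactly four times. Only main-axis
#' (outer-target) combinations are ever excluded.
#'
#' @param combinations The 60-row tibble from [enumerate_combinations()].
#' @param seed Optional integer seed for a reproducible exclusion set.
#' @return A 48-row tibble of retained combinations; the dropped rows are
#'   attached as attribute `"excluded"`.
#' @export
apply_exclusions <- function(combinations, seed = NULL) {
  main_dirs <- sort(unique(combinations$direction_deg[combinations$main_axis]))
  starts <- sort(unique(combinations$start_id))
  if (length(main_dirs) != 6L || length(starts) != 6L ||
      !all(table(combinations$direction_deg[combinations$main_axis]) == 6L)) {
    abort("`combinations` must have the 6x6 main-axis availability structure.")
  }
  with_seed(seed, {
    # two disjoint start-per-direction assignments = exclude 2 per direction
    # and 2 per start (union of two disjoint perfect matchings)
    p1 <- sample(6L)
    reps <- 0L
    repeat {
      p2 <- sample(6L)
      if (all(p2 != p1)) break
      reps <- reps + 1L
      if (reps > 10000L) abort("solver error: no disjoint exclusion assignment found.")
    }
    drop <- purrr::map(seq_len(6L), function(j) {
      which(combinations$direction_deg == main_dirs[j] &
              combinations$start_id %in% starts[c(p1[j], p2[j])])
    })
    drop <- unlist(drop)
    kept <- combinations[-drop, ]
    attr(kept, "excluded") <- combinations[drop, ]
    kept
  })
}
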