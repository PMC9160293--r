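# Discretized heterogeneous domain: house blocks vs streets on a regular
# cell-centered grid. Cell (i, j) uses 1-based column index i (x) and row
# index j (y), row 1 being the top of the map; cell (i, j) spans
# [(i-1)*dx, i*dx) x [(j-1)*dy, j*dy). Fields and cell labels are stored as
# ny x nx matrices so that printing a matrix shows the map as drawn.

#' Build a grid map from a 0/1 matrix
#'
#' Entries of `matrix` label each cell: 1 = house block, 0 = street. Row 1 is
#' the top of the map. Carrying capacities are specified as densities
#' (mosquitoes/m^2); per-cell totals are always `K = k * dx * dy`.
#'
#' @param matrix Rectangular numeric/integer matrix with entries in {0, 1}.
#' @param dx,dy Cell edge lengths in meters.
#' @param k_house,k_street Aquatic carrying-capacity densities (1/m^2) of
#'   house and street cells; must satisfy `k_house >= k_street >= 0`. Streets
#'   must keep a small positive capacity for the logistic term to be defined.
#' @return An object of class `aedes_map`.
#' @export
#' @examples
#' m <- map_from_matrix(matrix(1, 2, 2), dx = 5, dy = 5,
#'                      k_house = 0.15, k_street = 0.03)
#' map_composition(m)$n_house
map_from_matrix <- function(matrix, dx, dy, k_house, k_street) {
  if (!is.matrix(matrix)) stop("'matrix' must be a matrix")
  if (nrow(matrix) < 1L || ncol(matrix) < 1L) stop("map must have >= 1 cell")
  if (!all(matrix %in% c(0, 1))) {
    stop("map matrix entries must be 0 (street) or 1 (house)")
  }
  if (!is.finite(dx) || !is.finite(dy) || dx <= 0 || dy <= 0) {
    stop("cell sizes dx, dy must be positive")
  }
  if (k_street < 0 || k_house < k_street) {
    stop("capacities must satisfy k_house >= k_street >= 0")
  }
  m <- list(nx = ncol(matrix), ny = nrow(matrix), dx = dx, dy = dy,
            cells = matrix(as.integer(matrix), nrow(matrix), ncol(matrix)),
            k_house = k_house, k_street = k_street)
  class(m) <- "aedes_map"
  m
}

#' @export
print.aedes_map <- function(x, ...) {
  comp <- map_composition(x)
  cat(sprintf("aedes_map: %d x %d cells of %g m x %g m\n", x$nx, x$ny, x$dx, x$dy))
  cat(sprintf("  house: %d cells (%g m^2), k = %g /m^2 (K = %g per cell)\n",
              comp$n_house, comp$omega_house, x$k_house, comp$K_house))
  cat(sprintf("  street: %d cells (%g m^2), k = %g /m^2 (K = %g per cell)\n",
              comp$n_street, comp$omega_street, x$k_street, comp$K_street))
  invisible(x)
}

#' Cell area of a map (m^2)
#' @param map An `aedes_map`.
#' @return `dx * dy` in m^2.
#' @export
cell_area <- function(map) map$dx * map$dy

n_cells <- function(map) map$nx * map$ny

# per-cell carrying-capacity density as an ny x nx matrix
k_matrix <- function(map) {
  ifelse(map$cells == 1L, map$k_house, map$k_street)
}

#' Composition summary of a grid map
#'
#' Returns house/street cell counts (`n_house`, `n_street`), areas
#' (`omega_house`, `omega_street`, m^2), per-cell total capacities `K_house`
#' and `K_street` (= density * cell area), and the block-count-weighted mean
#' capacity `K_weighted = (n_h K_h + n_s K_s) / (n_h + n_s)` that enters the
#' domain-level critical release rate.
#'
#' @param map An `aedes_map`.
#' @return A named list.
#' @export
map_composition <- function(map) {
  stopifnot(inherits(map, "aedes_map"))
  a <- cell_area(map)
  n_h <- sum(map$cells == 1L)
  n_s <- sum(map$cells == 0L)
  K_h <- map$k_house * a
  K_s <- map$k_street * a
  list(n_house = n_h, n_street = n_s,
       omega_house = n_h * a, omega_street = n_s * a,
       K_house = K_h, K_street = K_s,
       K_weighted = (n_h * K_h + n_s * K_s) / (n_h + n_s))
}

#' Generate a synthetic Manhattan-style city map
#'
#' Streets are periodic horizontal and vertical bands (`street_width` cells
#' wide, one band every `street_period` cells); all remaining cells are house
#' blocks. The seed only selects the band offsets, and offsets are restricted
#' to those preserving the number of bands per axis, so the house/street
#' composition is identical across seeds and the map is fully deterministic
#' given its arguments. With the default geometry (40 x 40 cells, period 6,
#' width 1) the house fraction is 1089/1600 ~ 0.68.
#'
#' @param nx,ny Grid dimensions (cells).
#' @param street_period Distance in cells between consecutive street bands;
#'   must exceed `street_width`.
#' @param street_width Width of each street band in cells, `>= 1`. A map with
#'   no streets at all should be built with [map_from_matrix()] instead.
#' @param seed Integer seed selecting band offsets.
#' @param dx,dy Cell edge lengths (m).
#' @param k_house,k_street Capacity densities (1/m^2).
#' @return An `aedes_map`.
#' @export
synthesize_city_map <- function(nx = 40, ny = 40, street_period = 6,
                                street_width = 1, seed = 1L,
                                dx = 5, dy = 5,
                                k_house = 0.1475, k_street = 0.0295) {
  if (street_width < 1) stop("'street_width' must be >= 1")
  if (street_period <= street_width) {
    stop("'street_period' must exceed 'street_width'")
  }
  if (nx < 1 || ny < 1) stop("grid dimensions must be >= 1")
  # offsets are a pure function of the seed (no global RNG state involved)
  pick_offset <- function(n, h) {
    counts <- vapply(0:(street_period - 1), function(o) {
      sum(((seq_len(n) - 1 - o) %% street_period) < street_width)
    }, integer(1))
    admissible <- which(counts == max(counts)) - 1L
    admissible[1L + (h %% length(admissible))]
  }
  seed <- as.integer(seed)
  ox <- pick_offset(nx, (7L * seed + 2L) %% 104729L)
  oy <- pick_offset(ny, (13L * seed + 5L) %% 104729L)
  col_street <- ((seq_len(nx) - 1 - ox) %% street_period) < street_width
  row_street <- ((seq_len(ny) - 1 - oy) %% street_period) < street_width
  cells <- matrix(1L, ny, nx)
  cells[row_street, ] <- 0L
  cells[, col_street] <- 0L
  map_from_matrix(cells, dx, dy, k_house, k_street)
}

#' Reference synthetic city map with the standard composition
#'
#' Builds the package's committed 40 x 40 synthetic city raster: Manhattan
#' street bands (period 6, width 1, seed 1) giving 1089 house
#' cells, then the 17 house cells encountered last in row-major order are
#' relabelled as street so the map has exactly 1072 house and 528 street cells
#' of 5 m x 5 m (house area 26800 m^2, street area 13200 m^2). By default the
#' carrying-capacity densities are calibrated with
#' [calibrate_carrying_capacities()] so the domain female equilibrium equals
#' `F_target`.
#'
#' @param params Model parameters used for calibration.
#' @param F_target Domain-total female equilibrium used to calibrate
#'   capacities; set to `NULL` to skip calibration and keep `k_house`,
#'   `k_street` as given.
#' @param k_house,k_street Capacity densities used when `F_target` is `NULL`
#'   (and as the pre-calibration placeholders otherwise).
#' @return An `aedes_map` with exactly 1072 house cells.
#' @export
default_city_map <- function(params = default_parameters(), F_target = 10000,
                             k_house = 0.1475, k_street = 0.0295) {
  base <- synthesize_city_map(40, 40, street_period = 6, street_width = 1,
                              seed = 1L, k_house = k_house,
                              k_street = k_street)
  cells <- base$cells
  target_house <- 1072L
  excess <- sum(cells == 1L) - target_house
  if (excess < 0) stop("band geometry produced too few house cells")
  if (excess > 0) {
    # flip the last `excess` house cells in row-major order (bottom-right)
    idx <- which(t(cells) == 1L)             # row-major scan positions
    flip <- utils::tail(idx, excess)
    tc <- t(cells)
    tc[flip] <- 0L
    cells <- t(tc)
  }
  m <- map_from_matrix(cells, dx = 5, dy = 5,
                       k_house = k_house, k_street = k_street)
  if (!is.null(F_target)) {
    cal <- calibrate_carrying_capacities(params, m, F_target = F_target)
    m$k_house <- cal$k_house
    m$k_street <- cal$k_street
  }
  m
}

#' Homogenized version of a map
#'
#' Replaces every cell's carrying capacity with the block-count-weighted mean
#' capacity of the original map (the classic total-population simplification),
#' keeping the geometry. All cells are labelled as house cells of the averaged
#' capacity.
#'
#' @param map An `aedes_map`.
#' @return An `aedes_map` with uniform capacity.
#' @export
homogenize_map <- function(map) {
  comp <- map_composition(map)
  k_bar <- comp$K_weighted / cell_area(map)
  map_from_matrix(matrix(1L, map$ny, map$nx), map$dx, map$dy,
                  k_house = k_bar, k_street = k_bar)
}
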