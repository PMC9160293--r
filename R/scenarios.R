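# Release strategies and the release-strategy experiments: heterogeneity and
# localization comparisons, release-frequency scans, and the release-rate
# sweep validating the analytic bifurcation curve.

#' Construct a release schedule
#'
#' A schedule releases `amount_per_period` GM mosquitoes every `period` days
#' starting on `start_day`, spread uniformly over the footprint `cells`
#' (linear cell indices, column-major as in the field matrices, or `"all"`).
#' The daily-equivalent rate is `amount_per_period / period`.
#'
#' @param cells Integer vector of footprint cell indices, or `"all"`.
#' @param period Days between release events (integer `>= 1`).
#' @param amount_per_period GM mosquitoes released per event, `>= 0`.
#' @param start_day First release day (day 0 = start of the simulation).
#' @return An object of class `aedes_schedule`.
#' @export
release_schedule <- function(cells, period, amount_per_period, start_day = 0) {
  if (!identical(cells, "all")) {
    cells <- as.integer(cells)
    if (length(cells) == 0L) stop("release cell set must not be empty")
    if (any(cells < 1L)) stop("cell indices must be >= 1")
  }
  period <- as.integer(period)
  if (period < 1L) stop("'period' must be an integer >= 1")
  if (amount_per_period < 0) stop("'amount_per_period' must be >= 0")
  structure(list(cells = cells, period = period,
                 amount_per_period = amount_per_period,
                 start_day = as.integer(start_day)),
            class = "aedes_schedule")
}

is_release_day <- function(schedule, day) {
  day >= schedule$start_day &&
    ((day - schedule$start_day) %% schedule$period) == 0L
}

# per-cell release rate (mosq/m^2/day) applied throughout a release day:
# an event of N mosquitoes is the constant rate N/footprint-area for one day,
# independent of the sub-day step size
release_rate_field <- function(schedule, map) {
  n <- n_cells(map)
  cells <- if (identical(schedule$cells, "all")) seq_len(n) else schedule$cells
  if (any(cells > n)) stop("release cell index outside the map")
  footprint_area <- length(cells) * cell_area(map)
  rate <- schedule$amount_per_period / footprint_area
  lvec <- rep(0, n)
  lvec[cells] <- rate
  lvec
}

#' Central release footprint
#'
#' The committed localized-release footprint: a compact, near-square block of
#' `n_cells` contiguous cells at the map center (default 38 cells of 25 m^2,
#' i.e. 950 m^2, standing in for the reported ~944 m^2 central release
#' rectangle; a 6 x 6 block plus two adjacent cells). Returns column-major
#' linear indices.
#'
#' @param map An `aedes_map`.
#' @param n_cells Number of footprint cells.
#' @return Integer vector of cell indices.
#' @export
central_release_cells <- function(map, n_cells = 38) {
  if (n_cells < 1 || n_cells > n_cells(map)) stop("invalid footprint size")
  side <- floor(sqrt(n_cells))
  side <- min(side, map$nx, map$ny)
  row0 <- floor((map$ny - side) / 2) + 1L
  col0 <- floor((map$nx - side) / 2) + 1L
  rows <- row0:(row0 + side - 1L)
  cols <- col0:(col0 + side - 1L)
  idx <- as.integer(outer(rows, (cols - 1L) * map$ny, `+`))
  extra_needed <- n_cells - length(idx)
  if (extra_needed > 0) {
    # grow along the column to the right of the block, top first
    nxt <- col0 + side
    if (nxt > map$nx) nxt <- col0 - 1L
    extra <- (nxt - 1L) * map$ny + rows
    idx <- c(idx, extra[seq_len(min(extra_needed, length(extra)))])
    if (length(idx) < n_cells) stop("cannot build a contiguous footprint")
  }
  as.integer(sort(idx))
}

#' Domain-total female equilibrium of a calibrated map
#'
#' Sum of per-class female equilibrium totals over all cells; the reference
#' quantity that release amounts are expressed as multiples of.
#'
#' @inheritParams calibrate_carrying_capacities
#' @return Total females at equilibrium.
#' @export
domain_female_equilibrium <- function(params, map) {
  comp <- map_composition(map)
  area <- cell_area(map)
  comp$n_house * female_equilibrium_total(params, comp$K_house, area) +
    comp$n_street * female_equilibrium_total(params, comp$K_street, area)
}

#' Build a release schedule from a female-equilibrium multiple
#'
#' The released amount per event is `multiple` times the domain female
#' equilibrium, times `period` (so the daily-equivalent rate is independent
#' of the period). `kind = "localized"` puts the whole amount on the central
#' footprint of [central_release_cells()]; `kind = "homogeneous"` spreads it
#' uniformly over all cells. With the standard calibrated map and
#' `multiple = 11`, the daily amount is 110000 GM males.
#'
#' @param kind `"localized"` or `"homogeneous"`.
#' @param map A calibrated `aedes_map`.
#' @param params An `aedes_params` object.
#' @param multiple Release size as a multiple of the female equilibrium.
#' @param period Days between releases.
#' @param start_day First release day.
#' @param footprint Optional explicit cell index vector for `"localized"`.
#' @return An `aedes_schedule`.
#' @export
make_release_schedule <- function(kind = c("localized", "homogeneous"),
                                  map, params = default_parameters(),
                                  multiple = 11, period = 1, start_day = 0,
                                  footprint = NULL) {
  kind <- match.arg(kind)
  if (multiple < 0) stop("'multiple' must be >= 0")
  F_eq <- domain_female_equilibrium(params, map)
  amount <- multiple * F_eq * period
  cells <- if (kind == "homogeneous") {
    "all"
  } else if (is.null(footprint)) {
    central_release_cells(map)
  } else {
    footprint
  }
  release_schedule(cells, period = period, amount_per_period = amount,
                   start_day = start_day)
}

#' Summary metrics of a simulated trajectory
#'
#' Computes, on one phase's domain totals, the maximum decrease as a
#' percentage of the initial value, the mean over the horizon, and — given a
#' reference run on the same time grid — the signed difference at the final
#' day and the maximum absolute difference (both as % of the reference's
#' initial value) with the day at which the maximum occurs.
#'
#' @param run An `aedes_run` (or its `totals` data frame).
#' @param reference Optional second run on the same day grid.
#' @param phase Column to analyse (default `"A_total"`, the aquatic phase).
#' @return A named list of metrics.
#' @export
trajectory_metrics <- function(run, reference = NULL, phase = "A_total") {
  tt <- if (inherits(run, "aedes_run")) run$totals else run
  y <- tt[[phase]]
  y0 <- y[1]
  out <- list(initial = y0,
              max_decrease_pct = if (y0 > 0) (y0 - min(y)) / y0 * 100 else 0,
              mean = mean(y),
              final = y[length(y)])
  if (!is.null(reference)) {
    rt <- if (inherits(reference, "aedes_run")) reference$totals else reference
    if (!isTRUE(all.equal(tt$day, rt$day))) {
      stop("run and reference are on different time grids")
    }
    ref0 <- rt[[phase]][1]
    d <- y - rt[[phase]]
    i <- which.max(abs(d))
    out$diff_final_pct <- (y[length(y)] - rt[[phase]][length(y)]) / ref0 * 100
    out$max_diff_pct <- abs(d[i]) / ref0 * 100
    out$max_diff_day <- tt$day[i]
  }
  out
}

#' Heterogeneous versus homogenized-map comparison
#'
#' Runs the same release scenario twice: on the heterogeneous map and on its
#' homogenized version (every cell at the block-count-weighted mean
#' capacity), each starting from its own equilibrium, and reports the maximum
#' aquatic difference as a percentage of the heterogeneous run's initial
#' population.
#'
#' @param params An `aedes_params` object.
#' @param base_map A calibrated heterogeneous `aedes_map`.
#' @param schedule_kind `"localized"`, `"homogeneous"`, or `"none"` (control).
#' @param multiple Release multiple of the female equilibrium.
#' @param horizon Days simulated.
#' @param spec An `aedes_disc_spec`.
#' @return A list with runs `heterogeneous`, `homogenized` and `metrics`.
#' @export
heterogeneity_comparison <- function(params, base_map,
                                     schedule_kind = "localized",
                                     multiple = 11, horizon = 100,
                                     spec = discretization_spec()) {
  sched <- if (identical(schedule_kind, "none")) {
    NULL
  } else {
    make_release_schedule(schedule_kind, base_map, params, multiple = multiple)
  }
  homog <- homogenize_map(base_map)
  run_het <- simulate_pde(params, base_map, equilibrium_state(params, base_map),
                          sched, horizon = horizon, spec = spec,
                          context = solver_context(params, base_map, spec))
  run_hom <- simulate_pde(params, homog, equilibrium_state(params, homog),
                          sched, horizon = horizon, spec = spec,
                          context = solver_context(params, homog, spec))
  list(heterogeneous = run_het, homogenized = run_hom,
       metrics = trajectory_metrics(run_het, run_hom))
}

#' Localized versus homogeneous release comparison
#'
#' Runs the localized (central footprint) and spatially homogeneous release
#' of the same total daily amount on the same heterogeneous map, and reports
#' the aquatic difference at the horizon and the maximum difference with its
#' day, as percentages of the initial population.
#'
#' @inheritParams heterogeneity_comparison
#' @param map A calibrated `aedes_map`.
#' @return A list with runs `localized`, `homogeneous` and `metrics`.
#' @export
localization_comparison <- function(params, map, multiple = 11, horizon = 100,
                                    spec = discretization_spec()) {
  s_loc <- make_release_schedule("localized", map, params, multiple = multiple)
  s_hom <- make_release_schedule("homogeneous", map, params, multiple = multiple)
  init <- equilibrium_state(params, map)
  ctx <- solver_context(params, map, spec)
  run_loc <- simulate_pde(params, map, init, s_loc, horizon = horizon,
                          spec = spec, context = ctx)
  run_hom <- simulate_pde(params, map, init, s_hom, horizon = horizon,
                          spec = spec, context = ctx)
  list(localized = run_loc, homogeneous = run_hom,
       metrics = trajectory_metrics(run_loc, run_hom))
}

#' Release-frequency scan
#'
#' Holds the 30-day released total fixed (the daily-equivalent `multiple` of
#' the female equilibrium) while varying the interval between releases, each
#' release landing on the central footprint. The collapse threshold is
#' operationalized as the largest period whose aquatic total at the horizon
#' is below `collapse_frac` of its initial value.
#'
#' @inheritParams localization_comparison
#' @param periods Integer release periods (days) to scan.
#' @param collapse_frac Fraction of the initial aquatic population defining
#'   collapse at the horizon (default 0.5).
#' @return A list with `results` (data frame: period, final_A, final_frac,
#'   max_decrease_pct, mean_A), `threshold` (largest collapsing period, NA if
#'   none), and `runs` (per-period `aedes_run`s).
#' @export
frequency_scan <- function(params, map, multiple = 11, periods = 1:30,
                           horizon = 100, spec = discretization_spec(),
                           collapse_frac = 0.5) {
  init <- equilibrium_state(params, map)
  ctx <- solver_context(params, map, spec)
  runs <- list()
  rows <- vector("list", length(periods))
  for (i in seq_along(periods)) {
    p <- periods[i]
    sched <- make_release_schedule("localized", map, params,
                                   multiple = multiple, period = p)
    run <- simulate_pde(params, map, init, sched, horizon = horizon,
                        spec = spec, context = ctx)
    m <- trajectory_metrics(run)
    rows[[i]] <- data.frame(period = p, final_A = m$final,
                            final_frac = m$final / m$initial,
                            max_decrease_pct = m$max_decrease_pct,
                            mean_A = m$mean)
    runs[[paste0("period", p)]] <- run
  }
  results <- do.call(rbind, rows)
  collapsing <- results$period[results$final_frac < collapse_frac]
  threshold <- if (length(collapsing)) max(collapsing) else NA_integer_
  list(results = results, threshold = threshold, runs = runs)
}

#' Release-rate sweep against the analytic curve
#'
#' For each per-cell daily homogeneous release rate in `L_grid`, simulates
#' `horizon` days from equilibrium and records the final aquatic total,
#' paired with the analytic expected equilibrium
#' ([expected_equilibrium_curve()]) at the same rate.
#'
#' @inheritParams localization_comparison
#' @param L_grid Per-cell daily release rates.
#' @param horizon Days simulated (default 300).
#' @return A data frame with columns `L`, `final_A`, `expected_A`.
#' @export
release_sweep <- function(params, map, L_grid, horizon = 300,
                          spec = discretization_spec()) {
  init <- equilibrium_state(params, map)
  ctx <- solver_context(params, map, spec)
  expected <- expected_equilibrium_curve(params, map, L_grid)
  finals <- vapply(L_grid, function(L) {
    sched <- release_schedule("all", period = 1L,
                              amount_per_period = L * n_cells(map))
    run <- simulate_pde(params, map, init, sched, horizon = horizon,
                        spec = spec, context = ctx)
    m <- nrow(run$totals)
    run$totals$A_total[m]
  }, numeric(1))
  data.frame(L = L_grid, final_A = finals, expected_A = expected$A_total)
}
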