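# Total-population (single isolated cell) reduction of the spatial model,
# wild-case equilibria, carrying-capacity calibration, GM-perturbed cubic
# equilibria with stability classification, and critical release rates.
#
# All operations work on TOTAL populations in one cell of area `area` (m^2).
# Integrating the density model over an isolated cell turns the egg-production
# term alpha*beta*F*M (densities) into alpha*beta*F*M/area (totals), so the
# effective fecundity is beta/area. With `area = 1` the totals coincide with
# densities and the classic dimensionless formulas are recovered; city-scale
# computations pass area = dx*dy.

# effective cubic coefficients: A^3 - K A^2 + b K A + b c K = 0
cubic_b <- function(params, area = 1) {
  (params$mu_a + params$eta_a) * params$mu_f * params$mu_m * area /
    ((1 - params$r) * params$r * params$beta * params$eta_a^2)
}

cubic_c <- function(params, L) {
  params$mu_m * L / ((1 - params$r) * params$eta_a * params$mu_g)
}

#' Right-hand side of the single-cell total-population system
#'
#' The five per-day derivatives of the isolated-cell reduction: with
#' `alpha = M/(M+G)` (1 when `M = G = 0`),
#' \deqn{E' = \alpha \beta F M / area - e E}
#' \deqn{A' = e E (1 - A/K) - (\eta_a + \mu_a) A}
#' \deqn{F' = r \eta_a A - \mu_f F}
#' \deqn{M' = (1-r) \eta_a A - \mu_m M}
#' \deqn{G' = L - \mu_g G}
#'
#' @param params An `aedes_params` object.
#' @param state Numeric vector of totals `c(E, A, F, M, G)` (named or in this
#'   order), each non-negative with `A <= K`.
#' @param K Carrying capacity of the cell (total individuals).
#' @param L GM males released into the cell per day.
#' @param area Cell area in m^2 (1 reproduces the density-form equations).
#' @return Named numeric vector of derivatives (per day).
#' @export
ode_rhs <- function(params, state, K, L = 0, area = 1) {
  s <- as.numeric(state)
  E <- s[1]; A <- s[2]; F <- s[3]; M <- s[4]; G <- s[5]
  # adaptive integrators may probe marginally negative states; the mating
  # fraction is evaluated on the clamped values
  a <- wild_male_fraction(max(M, 0), max(G, 0))
  c(E = a * params$beta * F * M / area - params$e * E,
    A = params$e * E * (1 - A / K) - (params$eta_a + params$mu_a) * A,
    F = params$r * params$eta_a * A - params$mu_f * F,
    M = (1 - params$r) * params$eta_a * A - params$mu_m * M,
    G = L - params$mu_g * G)
}

#' Integrate the single-cell system
#'
#' Thin wrapper around a stiff-capable integrator ([deSolve::ode()], `lsoda`)
#' for the system of [ode_rhs()].
#'
#' @inheritParams ode_rhs
#' @param state0 Initial totals `c(E, A, F, M, G)`.
#' @param horizon Integration horizon (days).
#' @param dt Output time step (days); internal steps are adaptive.
#' @param atol,rtol Integrator tolerances.
#' @return A data frame with columns `time, E, A, F, M, G`.
#' @export
integrate_ode <- function(params, state0, K, L = 0, horizon, dt = 1,
                          area = 1, atol = 1e-10, rtol = 1e-10) {
  if (dt <= 0) stop("'dt' must be positive")
  if (horizon < dt) stop("'horizon' must be >= dt")
  y0 <- as.numeric(state0)
  names(y0) <- c("E", "A", "F", "M", "G")
  times <- seq(0, horizon, by = dt)
  f <- function(t, y, parms) list(ode_rhs(params, y, K = K, L = L, area = area))
  out <- deSolve::ode(y = y0, times = times, func = f, parms = NULL,
                      method = "lsoda", atol = atol, rtol = rtol)
  out <- as.data.frame(out)
  if (any(!is.finite(as.matrix(out)))) {
    stop("integrate_ode produced non-finite states (K=", K, ", L=", L, ")")
  }
  out
}

#' Basic offspring number
#'
#' The dimensionless reproduction index
#' `Q0 = beta r (1-r) eta_a^2 K / (4 (eta_a + mu_a) mu_f mu_m area)`.
#' A persistent wild population exists iff `Q0 >= 1`. Equivalently
#' `Q0 = K / (4 b)` with `b` the effective cubic coefficient.
#'
#' @inheritParams ode_rhs
#' @return Numeric `Q0 >= 0`.
#' @export
#' @examples
#' basic_offspring_number(default_parameters(), K = 3.6876) # ~ 303
basic_offspring_number <- function(params, K, area = 1) {
  if (any(K < 0)) stop("'K' must be non-negative")
  K / (4 * cubic_b(params, area))
}

# companion phase totals for a given admissible aquatic equilibrium A
companion_values <- function(params, A, K, L, area = 1) {
  F <- params$r * params$eta_a * A / params$mu_f
  M <- (1 - params$r) * params$eta_a * A / params$mu_m
  G <- L / params$mu_g
  E <- if (A <= 0) {
    0
  } else {
    (params$mu_a + params$eta_a) * A / (params$e * (1 - A / K))
  }
  c(E = E, A = A, F = F, M = M, G = G)
}

#' Wild-case equilibria (no GM release)
#'
#' With `L = 0` the aquatic equilibria solve the quadratic
#' `A^2 - K A + b K = 0`. When `Q0 < 1` only the trivial (extinct) state
#' exists; when `Q0 >= 1` the persistent equilibrium
#' `A* = K (1 + sqrt(1 - 1/Q0)) / 2` and the threshold (saddle) root
#' `K (1 - sqrt(1 - 1/Q0)) / 2` appear, with companion values
#' `F* = r eta_a A*/mu_f`, `M* = (1-r) eta_a A*/mu_m`,
#' `E* = (mu_a + eta_a) A*/(e (1 - A*/K))` and `G* = 0`.
#'
#' @inheritParams ode_rhs
#' @return An object of class `aedes_equilibria`: a list with `Q0`, `K`, `L`,
#'   `area` and a data frame `points` (columns `root`, `E`, `A`, `F`, `M`,
#'   `G`, `admissible`).
#' @export
wild_equilibrium <- function(params, K, area = 1) {
  if (K <= 0) stop("'K' must be positive")
  Q0 <- basic_offspring_number(params, K, area)
  pts <- list(c(root = NA, companion_values(params, 0, K, 0, area)))
  roots <- "trivial"
  if (Q0 >= 1) {
    s <- sqrt(1 - 1 / Q0)
    A_plus <- K * (1 + s) / 2
    A_minus <- K * (1 - s) / 2
    pts <- c(pts, list(c(root = NA, companion_values(params, A_plus, K, 0, area))),
             list(c(root = NA, companion_values(params, A_minus, K, 0, area))))
    roots <- c(roots, "persistent", "threshold")
  }
  points <- as.data.frame(do.call(rbind, pts))[-1]
  points <- cbind(root = roots, points)
  points$admissible <- points$A >= 0 & points$A <= K
  out <- list(Q0 = Q0, K = K, L = 0, area = area, points = points)
  class(out) <- "aedes_equilibria"
  out
}

#' @export
print.aedes_equilibria <- function(x, ...) {
  cat(sprintf("Equilibria at K = %g, L = %g, area = %g m^2 (Q0 = %g)\n",
              x$K, x$L, x$area, x$Q0))
  if (!is.null(x$phi)) cat(sprintf("  cubic discriminant phi = %g\n", x$phi))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Carrying capacity implied by an observed aquatic equilibrium
#'
#' Inverts the wild equilibrium relation: given the aquatic equilibrium total
#' `A_star` of a cell, returns `K = A_star^2 / (A_star - b)` where `b` is the
#' effective cubic coefficient. Round-trips with [wild_equilibrium()] (the
#' persistent root). Errors when the denominator is (near) zero, i.e. when
#' `A_star` equals `b`, where no finite capacity reproduces the observation.
#'
#' @inheritParams ode_rhs
#' @param A_star Observed aquatic-phase equilibrium total, `> 0`.
#' @return Carrying capacity `K`.
#' @export
carrying_capacity_from_aquatic <- function(params, A_star, area = 1) {
  if (A_star <= 0) stop("'A_star' must be positive")
  b <- cubic_b(params, area)
  den <- A_star - b
  if (abs(den) <= 1e-12 * max(1, A_star)) {
    stop("degenerate denominator: A_star is at the threshold value b = ", b)
  }
  A_star^2 / den
}

# female equilibrium total of one cell of capacity K (0 if Q0 < 1)
female_equilibrium_total <- function(params, K, area) {
  Q0 <- basic_offspring_number(params, K, area)
  if (Q0 < 1) return(0)
  A <- K * (1 + sqrt(1 - 1 / Q0)) / 2
  params$r * params$eta_a * A / params$mu_f
}

#' Calibrate house/street carrying capacities from a female target
#'
#' Solves `n_h F*(K_h) + w n_s F*(K_s) = F_target` under the constraint
#' `K_h = ratio * K_s` (default ratio 5, reflecting ~80% of breeding sites
#' being in houses) by one-dimensional root bracketing over `K_h`. `w` is the
#' street weight in the aggregation (default 1: plain block-count sum; 0.2
#' reproduces the alternative down-weighted convention).
#'
#' @param params An `aedes_params` object.
#' @param map An `aedes_map` supplying cell counts and cell area.
#' @param F_target Domain-total female equilibrium, `> 0`.
#' @param street_weight Weight of the street term in the aggregation.
#' @param ratio Capacity ratio `K_h / K_s`.
#' @return A list with `K_house`, `K_street` (per-cell totals), `k_house`,
#'   `k_street` (densities), and the achieved female total.
#' @export
calibrate_carrying_capacities <- function(params, map, F_target,
                                          street_weight = 1, ratio = 5) {
  stopifnot(inherits(map, "aedes_map"))
  if (F_target <= 0) stop("'F_target' must be positive")
  comp <- map_composition(map)
  if (comp$n_house < 1) stop("map must contain at least one house cell")
  area <- cell_area(map)
  b <- cubic_b(params, area)
  total_F <- function(K_h) {
    comp$n_house * female_equilibrium_total(params, K_h, area) +
      street_weight * comp$n_street *
        female_equilibrium_total(params, K_h / ratio, area)
  }
  # streets need Q0 >= 1, i.e. K_s >= 4b; just above that bound the female
  # total jumps from the house-only value to include the street branch
  K_h_min <- ratio * 4 * b * (1 + 1e-12)
  F_min <- total_F(K_h_min)
  if (F_target <= F_min) {
    stop(sprintf(paste0("F_target = %g is below the feasible minimum %g ",
                        "(streets require Q0 >= 1, i.e. K_h > %g); ",
                        "choose a larger target"),
                 F_target, F_min, ratio * 4 * b))
  }
  K_hi <- K_h_min * 2
  while (total_F(K_hi) < F_target) K_hi <- K_hi * 2
  root <- stats::uniroot(function(K) total_F(K) - F_target,
                         lower = K_h_min, upper = K_hi, tol = 1e-12)
  K_h <- root$root
  list(K_house = K_h, K_street = K_h / ratio,
       k_house = K_h / area, k_street = K_h / ratio / area,
       F_achieved = total_F(K_h))
}

# real cube root
cbrt <- function(x) sign(x) * abs(x)^(1/3)

#' Aquatic equilibria under constant GM release (cubic roots)
#'
#' With a constant daily release `L > 0` the aquatic equilibria solve the
#' cubic `A^3 - K A^2 + b K A + b c K = 0` with
#' `b = (mu_a + eta_a) mu_f mu_m area / ((1-r) r beta eta_a^2)` and
#' `c = mu_m L / ((1-r) eta_a mu_g)`. The roots are computed in closed form
#' (Cardano; trigonometric branch when the discriminant `phi < 0`), ordered
#' `A1 >= A2 >= A3`. For `phi < 0` the two larger roots are real positive and
#' admissible (`0 <= A <= K`) and `A3` is negative; for `phi > 0` no root is
#' admissible and the only attractor is the GM-only extinction state
#' `(0, 0, 0, 0, L/mu_g)`, which is always reported alongside the cubic roots.
#'
#' @inheritParams ode_rhs
#' @return An `aedes_equilibria` object; `points` has rows `A1`, `A2`, `A3`
#'   (complex roots reported with their real parts and `admissible = FALSE`)
#'   plus the `extinct` state, and attributes `b`, `c`, `phi`.
#' @export
gm_cubic_roots <- function(params, K, L, area = 1) {
  if (K <= 0) stop("'K' must be positive")
  if (L < 0) stop("'L' must be non-negative")
  b <- cubic_b(params, area)
  cc <- cubic_c(params, L)
  # depressed cubic x^3 + P x + Q, A = x + K/3
  P <- b * K - K^2 / 3
  Q <- -2 * K^3 / 27 + b * K^2 / 3 + b * cc * K
  phi <- P^3 / 27 + Q^2 / 4
  if (phi >= 0) {
    x1 <- cbrt(-Q / 2 + sqrt(phi)) + cbrt(-Q / 2 - sqrt(phi))
    roots <- c(x1 + K / 3, NA_real_, NA_real_)
    real <- c(TRUE, FALSE, FALSE)
    # remaining pair is complex-conjugate; report the real part
    re_pair <- -x1 / 2 + K / 3
    roots[2:3] <- re_pair
  } else {
    # three real roots (casus irreducibilis): trigonometric form
    mphalf <- sqrt(-P / 3)
    theta <- acos(pmin(1, pmax(-1, 3 * Q / (2 * P) / mphalf)))
    xs <- 2 * mphalf * cos(theta / 3 - 2 * pi * (0:2) / 3)
    roots <- sort(xs, decreasing = TRUE) + K / 3
    real <- c(TRUE, TRUE, TRUE)
  }
  admissible <- real & roots >= -1e-12 * K & roots <= K * (1 + 1e-12)
  pts <- lapply(seq_len(3), function(i) {
    if (admissible[i]) {
      companion_values(params, roots[i], K, L, area)
    } else {
      c(E = NA_real_, A = roots[i], F = NA_real_, M = NA_real_,
        G = L / params$mu_g)
    }
  })
  pts <- c(pts, list(companion_values(params, 0, K, L, area)))
  points <- as.data.frame(do.call(rbind, pts))
  points <- cbind(root = c("A1", "A2", "A3", "extinct"), points)
  points$admissible <- c(admissible, TRUE)
  out <- list(Q0 = basic_offspring_number(params, K, area), K = K, L = L,
              area = area, b = b, c = cc, phi = phi, points = points)
  class(out) <- "aedes_equilibria"
  out
}

# numeric Jacobian of ode_rhs at a point (central differences; one-sided at
# the non-negativity boundary)
ode_jacobian <- function(params, state, K, L, area = 1) {
  s <- as.numeric(state)
  n <- length(s)
  J <- matrix(NA_real_, n, n)
  scale_ref <- max(K, 1)
  for (i in seq_len(n)) {
    h <- 1e-6 * max(abs(s[i]), 1e-3 * scale_ref)
    lo <- s; hi <- s
    if (s[i] - h >= 0) {
      lo[i] <- s[i] - h; hi[i] <- s[i] + h
      denom <- 2 * h
    } else {
      hi[i] <- s[i] + h
      denom <- h
    }
    J[, i] <- (ode_rhs(params, hi, K, L, area) -
                 ode_rhs(params, lo, K, L, area)) / denom
  }
  if (any(!is.finite(J))) stop("non-finite Jacobian at the supplied state")
  J
}

#' Classify equilibria by local stability
#'
#' Evaluates the 5x5 Jacobian of the single-cell system numerically
#' (finite differences) at each equilibrium and labels it `"attractor"` if
#' every eigenvalue real part is below `-tol`, `"saddle"` if real parts of
#' both signs occur, `"repeller"` if all are above `tol`, and `"marginal"`
#' otherwise, with `tol = 1e-9` times the largest model rate. Rows whose
#' aquatic root is not admissible are labelled `"non-admissible"`.
#'
#' @inheritParams ode_rhs
#' @param equilibria An `aedes_equilibria` object from [wild_equilibrium()] or
#'   [gm_cubic_roots()].
#' @return The `aedes_equilibria` object with a `stability` column added.
#' @export
classify_equilibria <- function(params, K, L, equilibria, area = 1) {
  stopifnot(inherits(equilibria, "aedes_equilibria"))
  rates <- unlist(params[c("e", "eta_a", "mu_a", "mu_f", "mu_m", "mu_g")])
  tol <- 1e-9 * max(rates)
  pts <- equilibria$points
  labels <- character(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!isTRUE(pts$admissible[i])) {
      labels[i] <- "non-admissible"
      next
    }
    st <- as.numeric(pts[i, c("E", "A", "F", "M", "G")])
    ev <- Re(eigen(ode_jacobian(params, st, K, L, area),
                   only.values = TRUE)$values)
    labels[i] <- if (all(ev < -tol)) "attractor"
      else if (any(ev > tol) && any(ev < -tol)) "saddle"
      else if (all(ev > tol)) "repeller"
      else "marginal"
  }
  equilibria$points$stability <- labels
  equilibria
}

#' Critical daily GM release rate for one carrying capacity
#'
#' The release rate at which the cubic discriminant vanishes and the two
#' admissible equilibria merge and disappear:
#' \deqn{L_c(K) = \frac{(1-r)\eta_a\mu_g}{b K \mu_m}\left(
#'   \sqrt{-\tfrac{4}{27}(bK - K^2/3)^3} + \tfrac{2K^3}{27} -
#'   \tfrac{K^2 b}{3}\right).}
#' Above `L_c` the only attractor is extinction. Requires `K > 3b` so the
#' inner radicand is positive.
#'
#' @inheritParams ode_rhs
#' @return Critical release rate (GM mosquitoes per day for the cell).
#' @export
critical_release_rate <- function(params, K, area = 1) {
  if (K <= 0) stop("'K' must be positive")
  b <- cubic_b(params, area)
  P <- b * K - K^2 / 3
  radicand <- -4 / 27 * P^3
  if (radicand <= 0) {
    stop("critical release rate undefined: requires K > 3b (K = ", K,
         ", b = ", b, ")")
  }
  (1 - params$r) * params$eta_a * params$mu_g / (b * K * params$mu_m) *
    (sqrt(radicand) + 2 * K^3 / 27 - K^2 * b / 3)
}

#' Domain-level critical release rate
#'
#' Applies [critical_release_rate()] to the block-count-weighted mean
#' capacity of a calibrated map. The returned value is the per-cell daily
#' release under the homogeneous-release interpretation; the domain total is
#' attached as attribute `domain_total` (= per-cell value times the number of
#' cells).
#'
#' @inheritParams calibrate_carrying_capacities
#' @return Per-cell critical daily release, with attribute `domain_total`.
#' @export
domain_critical_release <- function(params, map) {
  comp <- map_composition(map)
  Lc <- critical_release_rate(params, comp$K_weighted, area = cell_area(map))
  attr(Lc, "domain_total") <- Lc * n_cells(map)
  Lc
}

#' Expected aquatic equilibrium versus release rate
#'
#' For each per-cell daily release rate in `L_grid`, sums the largest
#' admissible aquatic root `A1` over all cells of the map (0 where the
#' discriminant is positive and no admissible equilibrium exists). This is
#' the analytic bifurcation curve that 300-day simulations are validated
#' against.
#'
#' @inheritParams calibrate_carrying_capacities
#' @param L_grid Numeric vector of per-cell daily release rates.
#' @return A data frame with columns `L` and `A_total`.
#' @export
expected_equilibrium_curve <- function(params, map, L_grid) {
  comp <- map_composition(map)
  area <- cell_area(map)
  a1 <- function(K, L) {
    eq <- gm_cubic_roots(params, K, L, area)
    p <- eq$points
    if (isTRUE(p$admissible[p$root == "A1"])) p$A[p$root == "A1"] else 0
  }
  A_tot <- vapply(L_grid, function(L) {
    comp$n_house * a1(comp$K_house, L) + comp$n_street * a1(comp$K_street, L)
  }, numeric(1))
  data.frame(L = L_grid, A_total = A_tot)
}
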