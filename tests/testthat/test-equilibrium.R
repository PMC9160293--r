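test_that("basic offspring number follows the closed form", {
  p <- tab_params()
  expect_identical(basic_offspring_number(p, 0), 0)
  # high-precision evaluation of the closed form at the reported house
  # capacity (dimensionless convention, area = 1)
  expect_equal(basic_offspring_number(p, 3.6876), 303.0, tolerance = 1e-4)
  # K enters linearly
  expect_equal(basic_offspring_number(p, 2 * 1.3),
               2 * basic_offspring_number(p, 1.3), tolerance = 1e-12)
  # area normalization: totals over a 25 m^2 cell
  expect_equal(basic_offspring_number(p, 3.6876, area = 25),
               303.0026 / 25, tolerance = 1e-4)
})

test_that("wild equilibria satisfy the stationarity conditions", {
  p <- tab_params()
  for (K in c(0.7375, 2, 3.6876)) {
    for (area in c(1, 25)) {
      eq <- wild_equilibrium(p, K, area)
      pts <- eq$points
      expect_true("persistent" %in% pts$root)
      for (i in seq_len(nrow(pts))) {
        st <- as.numeric(pts[i, c("E", "A", "F", "M", "G")])
        resid <- ode_rhs(p, st, K, L = 0, area = area)
        expect_lt(max(abs(resid)) / max(1, max(abs(st))), 1e-9)
      }
      # G* = 0 on the wild branch; persistent root has the closed form
      expect_true(all(pts$G == 0))
      s <- sqrt(1 - 1 / eq$Q0)
      expect_equal(pts$A[pts$root == "persistent"], K * (1 + s) / 2)
      expect_equal(pts$A[pts$root == "threshold"], K * (1 - s) / 2)
    }
  }
})

test_that("a non-trivial equilibrium exists exactly when Q0 >= 1", {
  withr::with_seed(99, {
    for (i in 1:40) {
      p <- model_parameters(beta = runif(1, 0.5, 60), e = runif(1, 0.05, 1),
                            eta_a = runif(1, 0.1, 1), mu_a = runif(1, 0.01, 0.3),
                            mu_f = runif(1, 0.05, 0.6), mu_m = runif(1, 0.05, 0.6),
                            mu_g = runif(1, 0.1, 1), r = runif(1, 0.2, 0.8))
      K <- runif(1, 0.05, 5)
      eq <- wild_equilibrium(p, K)
      if (eq$Q0 >= 1) {
        expect_true("persistent" %in% eq$points$root)
        expect_true(all(eq$points$admissible))
      } else {
        expect_identical(eq$points$root, "trivial")
      }
    }
  })
  # boundary: Q0 = 1 gives the double root A* = K/2
  p <- tab_params()
  K1 <- 4 * aedesgm:::cubic_b(p, 1)
  eq1 <- wild_equilibrium(p, K1)
  expect_equal(eq1$Q0, 1, tolerance = 1e-12)
  expect_equal(eq1$points$A[eq1$points$root == "persistent"], K1 / 2)
})

test_that("carrying capacity inverts the aquatic equilibrium", {
  p <- tab_params()
  for (K in c(0.2, 0.7375, 3.6876, 12)) {
    A_star <- wild_equilibrium(p, K)$points
    A_star <- A_star$A[A_star$root == "persistent"]
    expect_equal(carrying_capacity_from_aquatic(p, A_star), K,
                 tolerance = 1e-10)
  }
  # the implied capacity vanishes with the observed aquatic population
  b <- aedesgm:::cubic_b(p, 1)
  expect_lt(abs(carrying_capacity_from_aquatic(p, b / 1000)), 1e-5)
  expect_error(carrying_capacity_from_aquatic(p, b), "degenerate")
  expect_error(carrying_capacity_from_aquatic(p, 0), "positive")
})

test_that("capacity calibration hits the female target under the 1:5 ratio", {
  p <- tab_params()
  map <- default_city_map(p, F_target = NULL)
  cal <- calibrate_carrying_capacities(p, map, F_target = 10000)
  expect_equal(cal$K_house / cal$K_street, 5, tolerance = 1e-12)
  expect_equal(cal$F_achieved, 10000, tolerance = 1e-8)
  # close to the reported fitted capacities
  expect_equal(cal$K_house, 3.6876, tolerance = 0.02)
  expect_equal(cal$K_street, 0.7375, tolerance = 0.02)
  # round trip: recomputing the female total from the fitted capacities
  comp <- map_composition(map)
  area <- cell_area(map)
  F_tot <- comp$n_house *
    aedesgm:::female_equilibrium_total(p, cal$K_house, area) +
    comp$n_street * aedesgm:::female_equilibrium_total(p, cal$K_street, area)
  expect_equal(F_tot, 10000, tolerance = 1e-6)
  # monotone in the target
  cal2 <- calibrate_carrying_capacities(p, map, F_target = 20000)
  expect_gt(cal2$K_house, cal$K_house)
  expect_gt(cal2$K_street, cal$K_street)
  # infeasible target names the feasible range
  expect_error(calibrate_carrying_capacities(p, map, F_target = 1e-6),
               "feasible minimum")
})

test_that("GM-release cubic roots agree with a companion-matrix root finder", {
  p <- tab_params()
  withr::with_seed(2024, {
    for (i in 1:30) {
      K <- runif(1, 0.5, 6)
      area <- sample(c(1, 25), 1)
      L <- runif(1, 0, 1.5) *
        tryCatch(critical_release_rate(p, K, area), error = function(e) 1)
      eq <- gm_cubic_roots(p, K, L, area)
      b <- eq$b; cc <- eq$c
      # all three roots satisfy the cubic A^3 - K A^2 + b K A + b c K = 0
      roots_num <- polyroot(c(b * cc * K, b * K, -K, 1))
      re <- sort(Re(roots_num[abs(Im(roots_num)) < 1e-8 * max(1, K)]))
      mine <- sort(eq$points$A[eq$points$root != "extinct"])
      if (eq$phi < 0) {
        expect_equal(length(re), 3L)
        expect_equal(mine, re, tolerance = 1e-9)
      } else {
        # one real root; the other two are reported by their real part
        expect_equal(min(abs(mine[1] - re)), 0, tolerance = 1e-8 * max(1, K))
      }
      for (A in mine[eq$points$admissible[eq$points$root != "extinct"]]) {
        expect_lt(abs(A^3 - K * A^2 + b * K * A + b * cc * K),
                  1e-9 * max(1, K^3))
      }
    }
  })
})

test_that("the release bifurcation has two admissible branches below L_c", {
  p <- tab_params()
  area <- 25
  for (K in c(0.7375, 3.6876)) {
    Lc <- critical_release_rate(p, K, area)
    lo <- gm_cubic_roots(p, K, 0.5 * Lc, area)
    expect_lt(lo$phi, 0)
    expect_identical(sum(lo$points$admissible[lo$points$root != "extinct"]), 2L)
    expect_true(all(lo$points$A[lo$points$admissible] >= 0))
    hi <- gm_cubic_roots(p, K, 1.05 * Lc, area)
    expect_gt(hi$phi, 0)
    expect_identical(sum(hi$points$admissible[hi$points$root != "extinct"]), 0L)
    # L = 0 recovers the wild roots plus zero
    z <- gm_cubic_roots(p, K, 0, area)
    w <- wild_equilibrium(p, K, area)
    expect_equal(sort(z$points$A[z$points$root != "extinct"]),
                 sort(c(0, w$points$A[w$points$root != "trivial"])),
                 tolerance = 1e-10)
  }
})

test_that("critical release rates zero the discriminant and grow with K", {
  p <- tab_params()
  area <- 25
  Ks <- seq(0.7375, 3.6876, length.out = 7)
  Lcs <- vapply(Ks, function(K) critical_release_rate(p, K, area), 1)
  # phi(K, L_c(K)) = 0 to relative precision
  for (i in seq_along(Ks)) {
    eq <- gm_cubic_roots(p, Ks[i], Lcs[i], area)
    scale <- abs(eq$b * Ks[i] - Ks[i]^2 / 3)^3 / 27
    expect_lt(abs(eq$phi) / scale, 1e-8)
  }
  expect_true(all(diff(Lcs) > 0))
  # bisection on the sign change of phi reproduces the closed form
  for (K in c(1.2, 3.6876)) {
    Lc <- critical_release_rate(p, K, area)
    f <- function(L) gm_cubic_roots(p, K, L, area)$phi
    root <- stats::uniroot(f, c(0.5 * Lc, 2 * Lc), tol = 1e-12)$root
    expect_equal(root, Lc, tolerance = 1e-8)
  }
  # small-capacity guard: the formula needs K > 3b
  b <- aedesgm:::cubic_b(p, area)
  expect_error(critical_release_rate(p, 2 * b, area), "K > 3b")
})

test_that("stability labels match the phase portrait", {
  p <- tab_params()
  area <- 25
  K <- 3.6876
  Lc <- critical_release_rate(p, K, area)
  L <- 0.5 * Lc
  eq <- classify_equilibria(p, K, L, gm_cubic_roots(p, K, L, area), area)
  lab <- stats::setNames(eq$points$stability, eq$points$root)
  expect_identical(unname(lab["A1"]), "attractor")
  expect_identical(unname(lab["A2"]), "saddle")
  expect_identical(unname(lab["A3"]), "non-admissible")
  expect_identical(unname(lab["extinct"]), "attractor")
  # wild case: the trivial state is an attractor too, the threshold a saddle
  weq <- classify_equilibria(p, K, 0, wild_equilibrium(p, K, area), area)
  wlab <- stats::setNames(weq$points$stability, weq$points$root)
  expect_identical(unname(wlab["trivial"]), "attractor")
  expect_identical(unname(wlab["persistent"]), "attractor")
  expect_identical(unname(wlab["threshold"]), "saddle")
})

test_that("trajectories converge to the labelled attractors", {
  p <- tab_params()
  area <- 25
  K <- 3.6876
  Lc <- critical_release_rate(p, K, area)
  L <- 0.5 * Lc
  eq <- gm_cubic_roots(p, K, L, area)
  A1 <- persistent_point(p, K, area, L)
  pts <- eq$points
  A2 <- unlist(pts[pts$root == "A2", c("E", "A", "F", "M", "G")])
  # just above the saddle: flows to the persistent attractor A1
  traj <- integrate_ode(p, A2 * c(1.05, 1.05, 1.05, 1.05, 1), K, L,
                        horizon = 600, dt = 5, area = area)
  expect_equal(unname(utils::tail(traj$A, 1)), unname(A1["A"]),
               tolerance = 1e-4)
  # above the critical release rate: extinction of all wild phases
  L_hi <- 1.2 * Lc
  start <- persistent_point(p, K, area, L = 0)
  traj2 <- integrate_ode(p, start, K, L_hi, horizon = 900, dt = 5, area = area)
  last <- utils::tail(traj2, 1)
  expect_lt(last$A, 1e-4 * start["A"])
  expect_lt(last$F, 1e-4 * start["F"])
  expect_equal(unname(last$G), L_hi / p$mu_g, tolerance = 1e-6)
  # starting at the wild equilibrium with no release: stationary within 0.1%
  traj3 <- integrate_ode(p, start, K, 0, horizon = 300, dt = 1, area = area)
  expect_lt(max(abs(traj3$A - start["A"])) / start["A"], 1e-3)
})

test_that("single-cell derivatives behave at the boundaries", {
  p <- tab_params()
  expect_equal(unname(ode_rhs(p, c(0, 0, 0, 0, 0), K = 2, L = 0)), rep(0, 5))
  # the G equation is decoupled and vanishes at G = L/mu_g
  d <- ode_rhs(p, c(5, 1, 2, 2, 7 / p$mu_g), K = 2, L = 7)
  expect_equal(unname(d["G"]), 0)
  # integrator rejects bad grids
  expect_error(integrate_ode(p, rep(1, 5), 2, 0, horizon = 1, dt = 0),
               "positive")
})

test_that("the expected equilibrium curve decreases to zero with the release", {
  p <- tab_params()
  map <- city_map()
  comp <- map_composition(map)
  Lc_h <- critical_release_rate(p, comp$K_house, cell_area(map))
  grid <- seq(0, 1.2 * Lc_h, length.out = 40)
  curve <- expected_equilibrium_curve(p, map, grid)
  # reduction to the wild case at L = 0
  wild_sum <- comp$n_house *
    persistent_point(p, comp$K_house, cell_area(map))["A"] +
    comp$n_street * persistent_point(p, comp$K_street, cell_area(map))["A"]
  expect_equal(curve$A_total[1], unname(wild_sum), tolerance = 1e-10)
  # non-increasing, and zero beyond the largest per-class critical rate
  expect_true(all(diff(curve$A_total) <= 1e-9))
  expect_true(all(curve$A_total[curve$L > Lc_h] == 0))
})
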