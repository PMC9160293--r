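# Spatial solver: finite-volume discretization of the five-field
# reaction-diffusion system with Crank-Nicolson time stepping.
#
# Fields are densities (mosquitoes/m^2) stored as ny x nx matrices in the
# same orientation as the map. The mobile phases F, M (coefficient D_m) and
# G (D_g) diffuse with a five-point stencil, arithmetic-mean face
# coefficients and zero-flux (homogeneous Neumann) boundaries; E and A are
# immobile. Each step solves the nonlinear Crank-Nicolson system with a
# damped Newton iteration (analytic reaction Jacobian, sparse LU, cached
# factorizations).

#' Proportion of wild males among all males
#'
#' `alpha = M / (M + G)`, with the convention `alpha = 1` when `M = G = 0`
#' (no males of either kind present). Vectorized; applied cell-wise inside
#' the solver to modulate egg production.
#'
#' @param M,G Non-negative wild-male and GM-male densities (or totals).
#' @return Values in `[0, 1]`.
#' @export
#' @examples
#' wild_male_fraction(c(0, 2, 1), c(0, 0, 1)) # 1, 1, 0.5
wild_male_fraction <- function(M, G) {
  if (any(M < 0) || any(G < 0)) stop("'M' and 'G' must be non-negative")
  tot <- M + G
  ifelse(tot == 0, 1, M / ifelse(tot == 0, 1, tot))
}

#' Discretization settings for the spatial solver
#'
#' @param dt Time step in days (default 1, the canonical daily step).
#' @param tol Convergence tolerance on the scaled nonlinear residual.
#' @param max_iter Maximum Newton iterations per step.
#' @param reaction Logical; disable to integrate pure diffusion (used by the
#'   mass-conservation checks; releases are switched off too).
#' @param clamp_tol Relative threshold below which small negative round-off
#'   values are clamped to zero; violations beyond it abort the run.
#' @return An object of class `aedes_disc_spec`.
#' @export
discretization_spec <- function(dt = 1, tol = 1e-10, max_iter = 50L,
                                reaction = TRUE, clamp_tol = 1e-8) {
  if (dt <= 0) stop("'dt' must be positive")
  if (tol <= 0) stop("'tol' must be positive")
  structure(list(dt = dt, tol = tol, max_iter = as.integer(max_iter),
                 reaction = isTRUE(reaction), clamp_tol = clamp_tol),
            class = "aedes_disc_spec")
}

#' Spatial state of the five fields
#'
#' @param map An `aedes_map`.
#' @param E,A,F,M,G Initial densities (1/m^2): scalars or ny x nx matrices.
#' @param t Current time in days.
#' @return An object of class `aedes_state` holding the five density matrices.
#' @export
spatial_state <- function(map, E = 0, A = 0, F = 0, M = 0, G = 0, t = 0) {
  as_field <- function(v, nm) {
    if (length(v) == 1L) v <- matrix(v, map$ny, map$nx)
    if (!is.matrix(v) || nrow(v) != map$ny || ncol(v) != map$nx) {
      stop("field '", nm, "' must be a scalar or a ", map$ny, " x ", map$nx,
           " matrix")
    }
    if (any(!is.finite(v)) || any(v < -1e-12)) {
      stop("field '", nm, "' must be finite and non-negative")
    }
    pmax(v, 0)
  }
  st <- list(E = as_field(E, "E"), A = as_field(A, "A"), F = as_field(F, "F"),
             M = as_field(M, "M"), G = as_field(G, "G"), t = t)
  class(st) <- "aedes_state"
  st
}

#' @export
print.aedes_state <- function(x, ...) {
  cat(sprintf("aedes_state at t = %g days (%d x %d cells)\n",
              x$t, nrow(x$E), ncol(x$E)))
  for (f in c("E", "A", "F", "M", "G")) {
    cat(sprintf("  %s: mean %.6g, max %.6g /m^2\n", f, mean(x[[f]]), max(x[[f]])))
  }
  invisible(x)
}

#' Initial state at the per-class wild equilibrium
#'
#' Each cell is set to the wild equilibrium densities of its class (house or
#' street), the standard starting point for release experiments. Cells whose
#' class has `Q0 < 1` start extinct.
#'
#' @param params An `aedes_params` object.
#' @param map An `aedes_map`.
#' @return An `aedes_state`.
#' @export
equilibrium_state <- function(params, map) {
  dens_for <- function(k) {
    eq <- wild_equilibrium(params, k, area = 1) # densities: area = 1 m^2
    p <- eq$points
    row <- if ("persistent" %in% p$root) p[p$root == "persistent", ] else
      p[p$root == "trivial", ]
    unlist(row[c("E", "A", "F", "M", "G")])
  }
  dh <- dens_for(map$k_house)
  ds <- dens_for(map$k_street)
  fields <- lapply(seq_along(dh), function(i) {
    ifelse(map$cells == 1L, dh[i], ds[i])
  })
  spatial_state(map, E = fields[[1]], A = fields[[2]], F = fields[[3]],
                M = fields[[4]], G = fields[[5]], t = 0)
}

# sparse diffusion operator (divergence form, arithmetic-mean face
# coefficients, zero-flux boundaries) acting on column-major vec of an
# ny x nx field; Dvec is the per-cell diffusion coefficient (column-major)
diffusion_operator <- function(map, Dvec) {
  nx <- map$nx; ny <- map$ny; n <- nx * ny
  if (length(Dvec) == 1L) Dvec <- rep(Dvec, n)
  idx <- function(i, j) (i - 1L) * ny + j  # column i (x), row j (y)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(a, b, coef) {
    ii <<- c(ii, a, b, a, b); jj <<- c(jj, b, a, a, b)
    xx <<- c(xx, coef, coef, -coef, -coef)
  }
  # vertical neighbours (same column, adjacent rows): spacing dy
  if (ny > 1) {
    for (i in seq_len(nx)) {
      a <- idx(i, seq_len(ny - 1L)); b <- idx(i, seq_len(ny - 1L) + 1L)
      coef <- (Dvec[a] + Dvec[b]) / 2 / map$dy^2
      ii <- c(ii, a, b, a, b); jj <- c(jj, b, a, a, b)
      xx <- c(xx, coef, coef, -coef, -coef)
    }
  }
  # horizontal neighbours (same row, adjacent columns): spacing dx
  if (nx > 1) {
    for (j in seq_len(ny)) {
      a <- idx(seq_len(nx - 1L), j); b <- idx(seq_len(nx - 1L) + 1L, j)
      coef <- (Dvec[a] + Dvec[b]) / 2 / map$dx^2
      ii <- c(ii, a, b, a, b); jj <- c(jj, b, a, a, b)
      xx <- c(xx, coef, coef, -coef, -coef)
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

# solver context: constant matrices and index patterns reused across steps.
# The nonlinear Crank-Nicolson solve covers the coupled E, A, F, M fields;
# the GM-male field G obeys a linear constant-coefficient equation and is
# advanced by its exact one-step transition operator (a matrix exponential),
# which is unconditionally positive and so immune to the oscillations a
# Crank-Nicolson step develops on sharp release pulses.
cn_context <- function(params, map, spec) {
  n <- n_cells(map)
  LF <- diffusion_operator(map, params$D_m)
  LG <- diffusion_operator(map, params$D_g)
  zero <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                               dims = c(n, n))
  Ldiff4 <- Matrix::bdiag(zero, zero, LF, LF)
  Jconst4 <- Matrix::Diagonal(4L * n) - (spec$dt / 2) * Ldiff4
  # reaction Jacobian pattern: 9 entries per cell over the E, A, F, M blocks
  off <- function(b) (b - 1L) * n
  cells <- seq_len(n)
  ii <- c(cells + off(1L), cells + off(1L), cells + off(1L),
          cells + off(2L), cells + off(2L),
          cells + off(3L), cells + off(3L),
          cells + off(4L), cells + off(4L))
  jj <- c(cells + off(1L), cells + off(3L), cells + off(4L),
          cells + off(1L), cells + off(2L),
          cells + off(2L), cells + off(3L),
          cells + off(2L), cells + off(4L))
  env <- new.env(parent = emptyenv())
  env$fac <- NULL
  env$EG <- NULL
  env$AG_fac <- NULL
  env$resp_lvec <- NULL
  env$resp <- NULL
  list(n = n, LG = LG, Ldiff4 = Ldiff4, Jconst4 = Jconst4, ii = ii, jj = jj,
       kvec = as.vector(k_matrix(map)), spec = spec, params = params,
       cache = env)
}

# exact one-step transition of the G field: G(t+dt) = EG G(t) + response(l),
# with EG = expm(dt (LG - mu_g I)) and, for a constant release rate l over
# the step, response = (LG - mu_g I)^{-1} (EG - I) l. Without reaction terms
# (pure transport checks) the decay is dropped and no release is applied.
g_step <- function(ctx, Gn, lvec) {
  cache <- ctx$cache
  if (is.null(cache$EG)) {
    Am <- if (ctx$spec$reaction) {
      ctx$LG - ctx$params$mu_g * Matrix::Diagonal(ctx$n)
    } else {
      ctx$LG
    }
    cache$EG <- as.matrix(Matrix::expm(ctx$spec$dt * Am))
    cache$AG_fac <- if (ctx$spec$reaction) Matrix::lu(Am) else NULL
  }
  Gnew <- as.numeric(cache$EG %*% Gn)
  if (ctx$spec$reaction && any(lvec > 0)) {
    if (!identical(lvec, cache$resp_lvec)) {
      rhs <- as.numeric(cache$EG %*% lvec) - lvec
      cache$resp <- as.numeric(Matrix::solve(cache$AG_fac, rhs))
      cache$resp_lvec <- lvec
    }
    Gnew <- Gnew + cache$resp
  }
  Gnew
}

# time derivative of the E, A, F, M blocks given the G field
cn_theta4 <- function(ctx, V, G) {
  n <- ctx$n; p <- ctx$params
  out <- as.numeric(ctx$Ldiff4 %*% V)
  if (ctx$spec$reaction) {
    E <- V[1:n]; A <- V[n + 1:n]; F <- V[2 * n + 1:n]; M <- V[3 * n + 1:n]
    tot <- M + G
    alpha <- ifelse(tot > 0, M / ifelse(tot > 0, tot, 1), 1)
    out[1:n] <- out[1:n] + alpha * p$beta * F * M - p$e * E
    out[n + 1:n] <- out[n + 1:n] + p$e * (1 - A / ctx$kvec) * E -
      (p$eta_a + p$mu_a) * A
    out[2 * n + 1:n] <- out[2 * n + 1:n] + p$r * p$eta_a * A - p$mu_f * F
    out[3 * n + 1:n] <- out[3 * n + 1:n] + (1 - p$r) * p$eta_a * A - p$mu_m * M
  }
  out
}

# reaction Jacobian values matching the (ii, jj) pattern of cn_context
cn_reaction_jac <- function(ctx, V, G) {
  n <- ctx$n; p <- ctx$params
  E <- V[1:n]; A <- V[n + 1:n]; F <- V[2 * n + 1:n]; M <- V[3 * n + 1:n]
  tot <- M + G
  pos <- tot > 0
  safe <- ifelse(pos, tot, 1)
  alpha <- ifelse(pos, M / safe, 1)
  dEM <- p$beta * F * ifelse(pos, M * (M + 2 * G) / safe^2, 1)
  c(rep(-p$e, n),                      # dE'/dE
    alpha * p$beta * M,                # dE'/dF
    dEM,                               # dE'/dM
    p$e * (1 - A / ctx$kvec),          # dA'/dE
    -p$e * E / ctx$kvec - (p$eta_a + p$mu_a),  # dA'/dA
    rep(p$r * p$eta_a, n),             # dF'/dA
    rep(-p$mu_f, n),                   # dF'/dF
    rep((1 - p$r) * p$eta_a, n),       # dM'/dA
    rep(-p$mu_m, n))                   # dM'/dM
}

cn_jacobian <- function(ctx, V, G) {
  if (!ctx$spec$reaction) return(ctx$Jconst4)
  Jr <- Matrix::sparseMatrix(i = ctx$ii, j = ctx$jj,
                             x = cn_reaction_jac(ctx, V, G),
                             dims = c(4L * ctx$n, 4L * ctx$n))
  ctx$Jconst4 - (ctx$spec$dt / 2) * Jr
}

state_to_vec <- function(state) {
  c(as.vector(state$E), as.vector(state$A), as.vector(state$F),
    as.vector(state$M), as.vector(state$G))
}

vec_to_state <- function(U, map, t) {
  n <- map$nx * map$ny
  shape <- function(v) matrix(v, map$ny, map$nx)
  st <- list(E = shape(U[1:n]), A = shape(U[n + 1:n]), F = shape(U[2 * n + 1:n]),
             M = shape(U[3 * n + 1:n]), G = shape(U[4 * n + 1:n]), t = t)
  class(st) <- "aedes_state"
  st
}

# one Crank-Nicolson step on the stacked vector [E; A; F; M; G]
cn_advance <- function(ctx, Un, lvec) {
  spec <- ctx$spec
  n <- ctx$n
  gblk <- 4L * n + seq_len(n)
  Gn <- Un[gblk]
  Gnew <- g_step(ctx, Gn, lvec)
  Vn <- Un[seq_len(4L * n)]
  scale <- numeric(4L * n)
  for (b in 1:4) {
    blk <- (b - 1L) * n + seq_len(n)
    scale[blk] <- max(1, max(abs(Vn[blk])))
  }
  theta_n <- cn_theta4(ctx, Vn, Gn)
  resid <- function(V) {
    V - Vn - (spec$dt / 2) * (cn_theta4(ctx, V, Gnew) + theta_n)
  }
  V <- Vn
  r <- resid(V)
  rs <- max(abs(r) / scale)
  cache <- ctx$cache
  iter <- 0L
  while (rs > spec$tol) {
    iter <- iter + 1L
    if (iter > spec$max_iter) {
      stop(sprintf(paste0("Crank-Nicolson Newton iteration failed to ",
                          "converge: %d iterations, scaled residual %.3e ",
                          "(tol %.3e)"), iter - 1L, rs, spec$tol))
    }
    fresh <- FALSE
    if (is.null(cache$fac)) {
      cache$fac <- Matrix::lu(cn_jacobian(ctx, V, Gnew))
      fresh <- TRUE
    }
    delta <- as.numeric(Matrix::solve(cache$fac, -r))
    step_ok <- FALSE
    lambda <- 1
    for (tr in 1:8) {
      V_new <- V + lambda * delta
      r_new <- resid(V_new)
      rs_new <- max(abs(r_new) / scale)
      if (is.finite(rs_new) && rs_new < rs) {
        step_ok <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!step_ok && !fresh) {
      # stale quasi-Newton factorization: re-linearize at the current iterate
      cache$fac <- Matrix::lu(cn_jacobian(ctx, V, Gnew))
      delta <- as.numeric(Matrix::solve(cache$fac, -r))
      V_new <- V + delta
      r_new <- resid(V_new)
      rs_new <- max(abs(r_new) / scale)
      step_ok <- is.finite(rs_new) && rs_new < rs
      fresh <- TRUE
    }
    if (!step_ok) {
      stop(sprintf(paste0("Crank-Nicolson Newton iteration diverged ",
                          "(scaled residual %.3e after %d iterations)"),
                   rs, iter))
    }
    # cached factors are only kept while convergence stays fast
    if (!fresh && rs_new > 0.2 * rs) cache$fac <- NULL
    V <- V_new; r <- r_new; rs <- rs_new
  }
  U <- c(V, Gnew)
  attr(U, "iterations") <- iter
  U
}

# enforce the invariant variable domain after a step
cn_enforce_domain <- function(U, ctx) {
  n <- ctx$n
  spec <- ctx$spec
  for (b in 1:5) {
    blk <- (b - 1L) * n + seq_len(n)
    v <- U[blk]
    clamp <- spec$clamp_tol * max(1, max(abs(v)))
    if (any(v < -clamp)) {
      stop(sprintf("field %d violated non-negativity beyond round-off (min %.3e)",
                   b, min(v)))
    }
    v[v < 0] <- 0
    U[blk] <- v
  }
  A <- U[n + seq_len(n)]
  cap <- ctx$kvec * (1 + 1e-9)
  over <- A > cap
  if (any(over)) {
    rel <- max(A / ctx$kvec - 1)
    if (rel > spec$clamp_tol) {
      stop(sprintf("aquatic density exceeded carrying capacity by %.3e (rel.)",
                   rel))
    }
    U[n + seq_len(n)] <- pmin(A, ctx$kvec)
  }
  U
}

#' Advance the spatial state by one Crank-Nicolson step
#'
#' Solves the fully coupled nonlinear Crank-Nicolson system for the five
#' fields over one time step `spec$dt`: five-point finite-volume diffusion
#' with arithmetic-mean face coefficients and zero-flux boundaries for F, M,
#' G, reaction terms averaged between time levels, Newton iteration with an
#' analytic reaction Jacobian to the requested tolerance. The resulting state
#' is checked against the invariant domain (non-negative fields, `A <= k`).
#'
#' @param params An `aedes_params` object.
#' @param map An `aedes_map`.
#' @param state Current `aedes_state`.
#' @param release_field Per-cell GM release rate (mosquitoes/m^2/day):
#'   scalar or ny x nx matrix.
#' @param spec An `aedes_disc_spec`.
#' @param context Optional precomputed solver context from
#'   [solver_context()]; built automatically when absent, and worth reusing
#'   across many steps and runs (it holds factorizations and the G-field
#'   transition operator).
#' @return The advanced `aedes_state` (attribute `iterations` reports the
#'   Newton count).
#' @export
crank_nicolson_step <- function(params, map, state, release_field = 0,
                                spec = discretization_spec(), context = NULL) {
  stopifnot(inherits(state, "aedes_state"))
  if (any(release_field < 0)) stop("'release_field' must be non-negative")
  if (is.null(context)) context <- cn_context(params, map, spec)
  lvec <- if (length(release_field) == 1L) {
    rep(release_field, context$n)
  } else {
    as.vector(release_field)
  }
  U <- cn_advance(context, state_to_vec(state), lvec)
  iters <- attr(U, "iterations")
  U <- cn_enforce_domain(U, context)
  out <- vec_to_state(U, map, state$t + spec$dt)
  attr(out, "iterations") <- iters
  out
}

#' Build a reusable solver context
#'
#' Precomputes the sparse operators, Jacobian index patterns and the exact
#' G-field transition operator for a given `(params, map, spec)` triple.
#' Passing the context to [simulate_pde()] or [crank_nicolson_step()] avoids
#' recomputing these (in particular the matrix exponential) for every run.
#'
#' @param params An `aedes_params` object.
#' @param map An `aedes_map`.
#' @param spec An `aedes_disc_spec`.
#' @return An opaque context object.
#' @export
solver_context <- function(params, map, spec = discretization_spec()) {
  cn_context(params, map, spec)
}

state_totals <- function(state, map) {
  a <- cell_area(map)
  c(E_total = sum(state$E) * a, A_total = sum(state$A) * a,
    F_total = sum(state$F) * a, M_total = sum(state$M) * a,
    G_total = sum(state$G) * a)
}

#' Simulate the spatial model over many days
#'
#' Repeatedly applies [crank_nicolson_step()], materializing the release
#' schedule into per-step release fields: an event of N mosquitoes on day d
#' is applied as the constant rate `N / footprint area` (per day) throughout
#' day d, independent of the sub-day step size. Domain totals (density times
#' cell area, summed) of all five phases are recorded once per day.
#'
#' @param params An `aedes_params` object.
#' @param map An `aedes_map`.
#' @param initial Initial `aedes_state` (e.g. from [equilibrium_state()]).
#' @param schedule A release schedule from [release_schedule()] /
#'   [make_release_schedule()], or `NULL` for a control run.
#' @param horizon Simulated time in days.
#' @param spec An `aedes_disc_spec`; `spec$dt` must divide 1 day.
#' @param snapshot_days Integer days at which to keep full field snapshots.
#' @param verbose Logical; print one line per simulated day.
#' @param context Optional solver context from [solver_context()] for the
#'   same `(params, map, spec)`; reusing one across runs avoids rebuilding
#'   the G-field transition operator.
#' @return A list of class `aedes_run`: `totals` (data frame `day, E_total,
#'   A_total, F_total, M_total, G_total`), `snapshots` (named list of
#'   `aedes_state`), `final` (final state).
#' @export
simulate_pde <- function(params, map, initial, schedule = NULL, horizon,
                         spec = discretization_spec(), snapshot_days = NULL,
                         verbose = FALSE, context = NULL) {
  stopifnot(inherits(initial, "aedes_state"))
  dt <- spec$dt
  steps_per_day <- round(1 / dt)
  if (abs(steps_per_day * dt - 1) > 1e-9) {
    stop("spec$dt must divide 1 day (got ", dt, ")")
  }
  if (horizon < dt) stop("'horizon' must be >= dt")
  n_days <- round(horizon)
  ctx <- if (is.null(context)) cn_context(params, map, spec) else context
  lfield_event <- if (!is.null(schedule)) {
    release_rate_field(schedule, map)
  } else {
    NULL
  }
  zero <- rep(0, ctx$n)
  totals <- matrix(NA_real_, n_days + 1L, 5L)
  totals[1L, ] <- state_totals(initial, map)
  snaps <- list()
  if (!is.null(snapshot_days) && 0 %in% snapshot_days) {
    snaps[["day0"]] <- initial
  }
  state_vec <- state_to_vec(initial)
  for (day in seq_len(n_days)) {
    release_today <- !is.null(schedule) &&
      is_release_day(schedule, day - 1L)   # events fire at the start of a day
    lvec <- if (release_today) lfield_event else zero
    for (s in seq_len(steps_per_day)) {
      state_vec <- cn_advance(ctx, state_vec, lvec)
      state_vec <- cn_enforce_domain(as.numeric(state_vec), ctx)
    }
    st <- vec_to_state(state_vec, map, day)
    totals[day + 1L, ] <- state_totals(st, map)
    if (verbose) {
      message(sprintf("day %d: E=%.1f A=%.1f F=%.1f M=%.1f G=%.1f",
                      day, totals[day + 1, 1], totals[day + 1, 2],
                      totals[day + 1, 3], totals[day + 1, 4],
                      totals[day + 1, 5]))
    }
    if (!is.null(snapshot_days) && day %in% snapshot_days) {
      snaps[[paste0("day", day)]] <- st
    }
  }
  colnames(totals) <- c("E_total", "A_total", "F_total", "M_total", "G_total")
  out <- list(totals = data.frame(day = 0:n_days, totals),
              snapshots = snaps,
              final = vec_to_state(state_vec, map, n_days))
  class(out) <- "aedes_run"
  out
}

#' @export
print.aedes_run <- function(x, ...) {
  n <- nrow(x$totals)
  cat(sprintf("aedes_run: %d days\n", x$totals$day[n]))
  cat("initial totals: "); print(round(unlist(x$totals[1, -1]), 1))
  cat("final totals:   "); print(round(unlist(x$totals[n, -1]), 1))
  invisible(x)
}
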