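#' Mass-action rate of change for the reversible strand exchange
#'
#' The lumped model treats the full toehold-binding/branch-migration pathway
#' as a single reversible bimolecular step
#' \deqn{X_1 + X_2 \rightleftharpoons X_3 + X_4}
#' with net flux \eqn{v = k_a x_1 x_2 - k_d x_3 x_4} (nM/s).
#'
#' @param state Named numeric vector `c(x1, x2, x3, x4)` of concentrations, nM.
#' @param system A [tmsdr_system()].
#' @return Named numeric vector of derivatives `(dx1, dx2, dx3, dx4)` in nM/s,
#'   equal to `(-v, -v, +v, +v)`.
#' @examples
#' sys <- tmsdr_system(ka = 1e-3, kd = 1e-4)
#' mass_action_rhs(reaction_state(10, 10), sys)  # dx1/dt = -0.1 nM/s
#' @export
mass_action_rhs <- function(state, system) {
  state <- check_state(state)
  v <- system$ka * state[["x1"]] * state[["x2"]] -
       system$kd * state[["x3"]] * state[["x4"]]
  c(x1 = -v, x2 = -v, x3 = v, x4 = v)
}

#' Simulate a reversible TMSDR trajectory
#'
#' Integrates the mass-action ODE with a stiff-capable solver
#' ([deSolve::lsoda()], rtol 1e-8, atol 1e-10 nM; the rate constants span
#' more than two orders of magnitude across reporter configurations, so a
#' fixed-step or non-stiff method is not safe).
#'
#' @param system A [tmsdr_system()].
#' @param initial Initial concentrations, see [reaction_state()].
#' @param times Numeric vector of output times in seconds, strictly
#'   increasing, starting at 0.
#' @return A `tmsdr_trajectory`: a data.frame with columns `time_s`, `x1_nM`,
#'   `x2_nM`, `x3_nM`, `x4_nM` and attributes `system` and `initial`.
#' @examples
#' sys <- tmsdr_system(ka = 6.48e-4, kd = 2.98e-5)
#' traj <- simulate_tmsdr(sys, reaction_state(10, 10), seq(0, 5400, by = 10))
#' tail(traj, 1)
#' @export
simulate_tmsdr <- function(system, initial, times) {
  initial <- check_state(initial)
  check_times(times)
  parms <- c(ka = system$ka, kd = system$kd)
  rhs <- function(t, y, p) {
    v <- p[["ka"]] * y[1] * y[2] - p[["kd"]] * y[3] * y[4]
    list(c(-v, -v, v, v))
  }
  if (length(times) == 1L) {
    out <- matrix(c(times, initial), nrow = 1L)
  } else {
    sol <- deSolve::lsoda(y = unname(initial), times = times, func = rhs,
                          parms = parms, rtol = 1e-8, atol = 1e-10)
    istate <- attributes(sol)$istate
    if (!is.null(istate) && istate[1L] < 0)
      stop_internal("ODE integration failed (lsoda istate = %d) for ka = %g, kd = %g",
                    istate[1L], system$ka, system$kd)
    if (nrow(sol) < length(times))
      stop_internal("ODE integration stopped early at t = %g s", sol[nrow(sol), 1L])
    out <- unclass(sol)
  }
  traj <- data.frame(time_s = out[, 1L], x1_nM = out[, 2L], x2_nM = out[, 3L],
                     x3_nM = out[, 4L], x4_nM = out[, 5L])
  structure(traj, class = c("tmsdr_trajectory", "data.frame"),
            system = system, initial = initial)
}

check_times <- function(times) {
  if (!is.numeric(times) || length(times) < 1L || any(!is.finite(times)))
    stop_config("`times` must be a finite numeric vector")
  if (times[1L] != 0)
    stop_config("`times` must start at 0 s")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop_config("`times` must be strictly increasing")
  invisible(times)
}

# Extent kinetics. With initials (a, b, c, d) and extent x (nM of X1
# displaced), dx/dt = ka (a - x)(b - x) - kd (c + x)(d + x) is quadratic in x:
#   dx/dt = alpha x^2 + beta x + gamma,
#   alpha = ka - kd, beta = -(ka (a + b) + kd (c + d)), gamma = ka a b - kd c d.
# Separation of variables / partial fractions gives the exact progress curve;
# the attracting root of the quadratic is the equilibrium extent.
extent_coefficients <- function(ka, kd, a, b, c0, d0) {
  list(alpha = ka - kd,
       beta = -(ka * (a + b) + kd * (c0 + d0)),
       gamma = ka * a * b - kd * c0 * d0)
}

# The root reachable from x = 0: the reaction moves in the direction of
# sign(gamma) and stops at the first root it meets, which is the attracting one.
reachable_root <- function(alpha, beta, gamma) {
  disc <- beta^2 - 4 * alpha * gamma
  if (disc < 0) {
    if (disc > -1e-10 * beta^2) disc <- 0
    else stop_internal("no real equilibrium root (discriminant %g < 0)", disc)
  }
  sq <- sqrt(disc)
  roots <- c((-beta - sq) / (2 * alpha), (-beta + sq) / (2 * alpha))
  cand <- if (gamma > 0) roots[roots > 0] else roots[roots < 0]
  if (length(cand) == 0L)
    stop_internal("no physically reachable equilibrium root")
  if (gamma > 0) min(cand) else max(cand)
}

extent_closed_form_ <- function(ka, kd, a, b, c0, d0, t) {
  co <- extent_coefficients(ka, kd, a, b, c0, d0)
  if (co$gamma == 0) return(rep(0, length(t)))  # starts at equilibrium
  if (abs(co$alpha) <= 1e-12 * max(ka, kd)) {
    # ka == kd: the quadratic term vanishes, leaving a linear relaxation
    return((-co$gamma / co$beta) * (1 - exp(co$beta * t)))
  }
  disc <- co$beta^2 - 4 * co$alpha * co$gamma
  if (abs(disc) <= 1e-12 * co$beta^2) {
    # coincident roots (e.g. kd = 0 with equal initials): algebraic decay
    r <- -co$beta / (2 * co$alpha)
    return(co$alpha * r^2 * t / (1 + co$alpha * r * t))
  }
  r1 <- reachable_root(co$alpha, co$beta, co$gamma)
  r2 <- (co$gamma / co$alpha) / r1          # product of roots = gamma/alpha
  lambda <- co$alpha * (r1 - r2)            # < 0: r1 is attracting
  e <- exp(lambda * t)
  r1 * (1 - e) / (1 - (r1 / r2) * e)
}

extent_equilibrium_ <- function(ka, kd, a, b, c0, d0) {
  if (kd == 0) return(min(a, b))
  co <- extent_coefficients(ka, kd, a, b, c0, d0)
  if (co$gamma == 0) return(0)
  if (abs(co$alpha) <= 1e-12 * max(ka, kd)) return(-co$gamma / co$beta)
  reachable_root(co$alpha, co$beta, co$gamma)
}

#' Exact extent of reaction at time t
#'
#' The extent x(t) (nM of X1 displaced since t = 0) obeys a Riccati-type ODE
#' quadratic in x, solvable in closed form by partial fractions. This analytic
#' progress curve is exact for the lumped model and serves both as the fast
#' model function during fitting and as an independent oracle for the numeric
#' integrator. Degenerate cases (ka = kd, coincident roots, no thermodynamic
#' driving force) use their limiting closed forms rather than dividing by zero.
#'
#' @inheritParams simulate_tmsdr
#' @param t Time(s) in seconds, nonnegative; vectorized.
#' @return Numeric vector of extents in nM, same length as `t`. Positive when
#'   the net reaction runs forward, negative when it runs backward (possible
#'   only when products are present initially).
#' @examples
#' sys <- tmsdr_system(ka = 1e-3, kd = 0)
#' closed_form_extent(sys, reaction_state(10, 10), c(0, 100, 1000))
#' @export
closed_form_extent <- function(system, initial, t) {
  initial <- check_state(initial)
  if (any(t < 0)) stop_config("`t` must be nonnegative")
  extent_closed_form_(system$ka, system$kd, initial[["x1"]], initial[["x2"]],
                      initial[["x3"]], initial[["x4"]], t)
}

#' Equilibrium extent of the reversible strand exchange
#'
#' Solves ka (a - x)(b - x) = kd (c + x)(d + x) for the physically admissible
#' root: the one lying in \eqn{[-\min(c,d), \min(a,b)]} and reachable from
#' x = 0 by continuity (the attracting root of the extent ODE). For the
#' irreversible case kd = 0 the reaction goes to completion of the limiting
#' reactant, x* = min(a, b).
#'
#' @inheritParams simulate_tmsdr
#' @return The equilibrium extent x* in nM.
#' @examples
#' sys <- tmsdr_system(ka = 4.78e-5, kd = 4.60e-3)
#' equilibrium_extent(sys, reaction_state(10, 10)) / 10  # ~0.0925
#' @export
equilibrium_extent <- function(system, initial) {
  initial <- check_state(initial)
  if (initial[["x1"]] + initial[["x2"]] <= 0)
    stop_config("equilibrium requires x1 + x2 > 0")
  xeq <- extent_equilibrium_(system$ka, system$kd, initial[["x1"]],
                             initial[["x2"]], initial[["x3"]], initial[["x4"]])
  lo <- -min(initial[["x3"]], initial[["x4"]])
  hi <- min(initial[["x1"]], initial[["x2"]])
  if (xeq < lo - 1e-9 || xeq > hi + 1e-9)
    stop_internal("equilibrium extent %g outside admissible interval [%g, %g]",
                  xeq, lo, hi)
  xeq
}

#' Substitution ratio: displaced fraction of the invader strand
#'
#' The fraction of X1 converted, \eqn{(x_{1,0} - x_1)/x_{1,0}}, equal to the
#' extent divided by the initial invader concentration (and to
#' \eqn{x_4/x_{1,0}} when products start at zero). For a trajectory the ratio
#' is computed pointwise from the X1 column.
#'
#' @param x A `tmsdr_trajectory`, or a numeric extent (nM, scalar or vector)
#'   as returned by [closed_form_extent()] / [equilibrium_extent()].
#' @param initial_x1 Initial X1 concentration in nM; for trajectories it
#'   defaults to the stored initial state.
#' @return Numeric in \[0, 1\] (same length as the input time grid for
#'   trajectories).
#' @export
substitution_ratio <- function(x, initial_x1) UseMethod("substitution_ratio")

#' @export
substitution_ratio.numeric <- function(x, initial_x1) {
  if (!is.numeric(initial_x1) || initial_x1 <= 0)
    stop_config("`initial_x1` must be positive")
  ratio_clamp(x / initial_x1)
}

#' @export
substitution_ratio.tmsdr_trajectory <- function(x, initial_x1 = NULL) {
  if (is.null(initial_x1)) initial_x1 <- attr(x, "initial")[["x1"]]
  if (!is.numeric(initial_x1) || initial_x1 <= 0)
    stop_config("`initial_x1` must be positive")
  ratio_clamp((initial_x1 - x$x1_nM) / initial_x1)
}

# Integrator round-off can leave ratios a hair outside [0, 1]; anything more
# than that is a genuine domain violation.
ratio_clamp <- function(r, tol = 1e-7) {
  if (any(r < -tol) || any(r > 1 + tol))
    stop_config("substitution ratio outside [0, 1] (range %.4g..%.4g)",
                min(r), max(r))
  pmin(pmax(r, 0), 1)
}

#' Write a trajectory to CSV
#'
#' Header `time_s,x1_nM,x2_nM,x3_nM,x4_nM`, one row per time point.
#'
#' @param trajectory A `tmsdr_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  write.csv(as.data.frame(trajectory), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#' @param path File path.
#' @return A `tmsdr_trajectory` data.frame (without system attributes).
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path)
  need <- c("time_s", "x1_nM", "x2_nM", "x3_nM", "x4_nM")
  if (!all(need %in% names(df)))
    stop_data("trajectory CSV %s lacks columns: %s", path,
              paste(setdiff(need, names(df)), collapse = ", "))
  structure(df[need], class = c("tmsdr_trajectory", "data.frame"))
}
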