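# Deterministic integration of the replicator dynamics, scenario presets,
# convergence/crossing diagnostics and single-parameter sweeps.

#' Integrate the replicator dynamics
#'
#' Solves the replicator ODE system with an adaptive 4th/5th-order
#' Runge-Kutta scheme (relative tolerance `1e-8`, absolute `1e-10`) and
#' reports the solution on an evenly spaced time grid.
#'
#' Interior coordinates are integrated on the logit scale, where the
#' replicator equations reduce to `du/dt = G`, `dv/dt = J`, `dw/dt = -H`
#' with `(x, y, z) = logistic(u, v, w)`.  This keeps every state inside the
#' open cube by construction (the boundary is unreachable in finite time, as
#' in the exact flow) and avoids the floating-point absorption onto boundary
#' faces that direct Cartesian integration suffers from, which can
#' artificially trap trajectories at saddle corners.  Initial-state
#' components lying exactly on the boundary are held fixed, since boundary
#' faces are invariant.
#'
#' @inheritParams replicator_rates
#' @param init initial mixed state `(x, y, z)` (default `(0.8, 0.5, 0.2)`).
#' @param t_end integration horizon (default 50 time units, long enough for
#'   every scenario preset to settle).
#' @param n_out number of output times (at least 201).
#' @param rtol,atol integrator tolerances.
#' @return Object of class `"game_trajectory"`: a data frame with columns
#'   `time`, `x`, `y`, `z` and attributes `params`, `mode`, `init`.
#' @examples
#' tr <- integrate_game(scenario_params(1), t_end = 50)
#' tail(tr, 1)   # close to (0, 0, 0)
#' @export
integrate_game <- function(params, init = c(0.8, 0.5, 0.2), t_end = 50,
                           mode = c("reference", "matrix"), n_out = 201,
                           rtol = 1e-8, atol = 1e-10) {
  params <- coerce_params(params)
  mode <- check_mode(mode)
  init <- check_state(init)
  stopifnot(is.numeric(t_end), t_end >= 0)
  p <- as.list(params)
  dI <- p$It1 - p$It2
  free <- init > 0 & init < 1        # boundary components stay fixed
  times <- seq(0, t_end, length.out = max(201L, as.integer(n_out)))
  if (t_end == 0) times <- 0

  factors <- function(x, y, z) {
    G <- p$Ch2 - p$Ch1 + p$Ih1 - p$Ih2 + z * p$Ah + p$Ph * (y + z - y * z)
    J <- p$Ct2 - p$Ct1 + z * p$Pt +
      if (mode == "reference") dI * (1 - x + x * z) else dI * (1 - x)
    H <- p$Cg - p$Ag - p$Pg - p$Ph - p$Pt + x * p$Ah +
      (x + y - x * y) * (p$Pg + p$Ph) + y * p$Pt
    c(G, J, -H)
  }

  if (!any(free)) {
    m <- matrix(init, nrow = length(times), ncol = 3, byrow = TRUE)
  } else {
    u0 <- stats::qlogis(init[free])
    deriv <- function(t, u, parms) {
      s <- init
      s[free] <- stats::plogis(u)
      list(factors(s[1], s[2], s[3])[free])
    }
    sol <- deSolve::ode(y = u0, times = times, func = deriv, parms = NULL,
                        method = "ode45", rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("ODE integration failed; last valid state: ",
           paste(signif(stats::plogis(sol[nrow(sol), -1]), 6),
                 collapse = ", "))
    m <- matrix(init, nrow = nrow(sol), ncol = 3, byrow = TRUE)
    m[, free] <- stats::plogis(sol[, -1, drop = FALSE])
  }
  out <- data.frame(time = times, x = m[, 1], y = m[, 2], z = m[, 3])
  structure(out, class = c("game_trajectory", "data.frame"),
            params = params, mode = mode, init = init)
}

#' Convergence check for a trajectory
#'
#' A trajectory is declared converged when, over its final 10% window, the
#' state moves less than `tol` (in max norm) and the replicator rates stay
#' below `2 * tol`, and additionally the flow at the endpoint is not pointing
#' away from any nearby boundary.
#'
#' The last condition guards against finite-horizon lingering: a trajectory
#' can sit exponentially close to a saddle corner with its outward per-capita
#' drift invisible in the frequency-scale rates (`dx/dt = x(1-x)G` vanishes
#' as `x` saturates even when `G > 0`).  For every initially interior
#' component that ends within 0.01 of a boundary, the per-capita growth rate
#' (the factor `G`, `J` or `-H`) must therefore push into that boundary;
#' otherwise the state will eventually leave and is reported not converged.
#' Components that started exactly on the boundary are pinned there
#' (boundary faces are invariant) and are exempt.
#'
#' @param traj a `"game_trajectory"`.
#' @param tol convergence tolerance on state movement (default `1e-3`).
#' @return The final state `c(x=, y=, z=)` when converged, otherwise `NULL`.
#' @export
converged_state <- function(traj, tol = 1e-3) {
  stopifnot(inherits(traj, "game_trajectory"), nrow(traj) >= 1L)
  params <- attr(traj, "params"); mode <- attr(traj, "mode")
  init <- attr(traj, "init")
  free <- if (is.null(init)) rep(TRUE, 3) else (init > 0 & init < 1)
  n <- nrow(traj)
  i0 <- max(1L, n - max(1L, ceiling(0.1 * n)) + 1L)
  win <- as.matrix(traj[i0:n, c("x", "y", "z")])
  if (nrow(win) < 2L) return(NULL)
  final <- win[nrow(win), ]
  names(final) <- c("x", "y", "z")
  move <- max(abs(sweep(win, 2, final)))
  rates <- apply(win, 1, function(s) max(abs(replicator_rates(params, s, mode))))
  if (move >= tol || max(rates) >= 2 * tol) return(NULL)
  # per-capita drift toward/away from nearby boundaries
  drift <- c(G_factor(params, final[["y"]], final[["z"]]),
             J_factor(params, final[["x"]], final[["z"]], mode),
             -H_factor(params, final[["x"]], final[["y"]]))
  for (i in 1:3) {
    if (!free[i]) next
    if (final[i] < 0.01 && drift[i] > tol) return(NULL)   # will leave 0
    if (final[i] > 0.99 && drift[i] < -tol) return(NULL)  # will leave 1
  }
  final
}

#' First crossing time of a trajectory component
#'
#' Time at which component `x`, `y` or `z` first drops below (or rises above)
#' `level`, located by linear interpolation between stored output points.
#'
#' @param traj a `"game_trajectory"`.
#' @param component `"x"`, `"y"` or `"z"`.
#' @param level threshold level in (0, 1).
#' @param direction `"below"` or `"above"`.
#' @return Crossing time, or `NA_real_` when the level is never reached.
#' @export
time_to_threshold <- function(traj, component = c("x", "y", "z"), level,
                              direction = c("below", "above")) {
  stopifnot(inherits(traj, "game_trajectory"))
  component <- match.arg(component)
  direction <- match.arg(direction)
  stopifnot(level > 0, level < 1)
  v <- traj[[component]]
  tt <- traj$time
  hit <- if (direction == "below") v < level else v > level
  if (hit[1]) return(tt[1])
  i <- which(hit)[1]
  if (is.na(i)) return(NA_real_)
  # interpolate between i-1 and i
  v0 <- v[i - 1]; v1 <- v[i]
  if (v1 == v0) return(tt[i])
  tt[i - 1] + (level - v0) / (v1 - v0) * (tt[i] - tt[i - 1])
}

#' Run a scenario preset
#'
#' Integrates a scenario preset (optionally with parameter overrides) from
#' the standard initial state `(0.8, 0.5, 0.2)` and attaches the corner
#' stability report and ESS condition flags.
#'
#' @param preset_id scenario 1, 2 or 3 (see [scenario_params()]).
#' @param overrides named numeric vector/list of parameter overrides; the
#'   overridden set must still validate.
#' @inheritParams integrate_game
#' @return List of class `"scenario_result"`: `params`, `trajectory`,
#'   `stability` (see [stability_report()]), `flags`, `endpoint`,
#'   `converged`.
#' @examples
#' res <- run_scenario(3)
#' res$endpoint          # close to (1, 0, 1)
#' @export
run_scenario <- function(preset_id, overrides = NULL, t_end = 50,
                         mode = c("reference", "matrix"),
                         init = c(0.8, 0.5, 0.2)) {
  mode <- check_mode(mode)
  params <- scenario_params(preset_id)
  if (!is.null(overrides)) {
    ov <- unlist(overrides)
    bad <- setdiff(names(ov), param_names)
    if (length(bad)) stop("unknown parameter override(s): ",
                          paste(bad, collapse = ", "))
    params[names(ov)] <- ov
    viol <- validate_params(params, strict = TRUE)
    if (length(viol)) stop("overridden parameters violate constraints: ",
                           paste(viol, collapse = "; "))
  }
  traj <- integrate_game(params, init = init, t_end = t_end, mode = mode)
  endpoint <- unlist(traj[nrow(traj), c("x", "y", "z")])
  structure(list(params = params, trajectory = traj,
                 stability = stability_report(params, mode),
                 flags = condition_flags(params),
                 endpoint = endpoint,
                 converged = converged_state(traj)),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("Scenario run, mode:", attr(x$trajectory, "mode"), "\n")
  cat("endpoint (t =", max(x$trajectory$time), "): ",
      paste(sprintf("%s=%.4f", names(x$endpoint), x$endpoint), collapse = ", "),
      "\n")
  cat("converged:", !is.null(x$converged), "\n")
  cat("ESS conditions: A =", x$flags[["A"]], " B =", x$flags[["B"]],
      " C =", x$flags[["C"]], "\n")
  print(x$stability, ...)
  invisible(x)
}

#' Single-parameter sweep
#'
#' Re-integrates the dynamics for each value of one parameter and records a
#' metric per value: the final state, and/or the first time a component
#' crosses a level (the "speed of evolution" read off sweep figures).
#'
#' @inheritParams integrate_game
#' @param name parameter to vary (one of [param_names]).
#' @param values numeric vector of values to sweep over.
#' @param metric either `"final_state"` or a list
#'   `list(component =, level =, direction =)` for [time_to_threshold()].
#' @param strict validate each swept set strictly (default `TRUE`); invalid
#'   values are flagged in the result, and the sweep continues.
#' @return Data frame of class `"sweep_result"`: one row per value with
#'   columns `value`, `valid`, final `x`, `y`, `z` and (for a threshold
#'   metric) `metric_time` (`NA` when not reached).
#' @examples
#' parameter_sweep(scenario_params(1), "Cg", c(9, 10, 11),
#'                 metric = list(component = "z", level = 0.1,
#'                               direction = "below"))
#' @export
parameter_sweep <- function(params, name, values, metric = "final_state",
                            init = c(0.8, 0.5, 0.2), t_end = 50,
                            mode = c("reference", "matrix"), strict = TRUE) {
  params <- coerce_params(params)
  mode <- check_mode(mode)
  stopifnot(name %in% param_names)
  rows <- lapply(values, function(v) {
    pp <- params; pp[name] <- v
    viol <- validate_params(pp, strict = strict)
    if (length(viol) > 0L)
      return(data.frame(value = v, valid = FALSE, x = NA_real_, y = NA_real_,
                        z = NA_real_, metric_time = NA_real_))
    traj <- integrate_game(pp, init = init, t_end = t_end, mode = mode)
    fin <- traj[nrow(traj), ]
    mt <- if (is.list(metric))
      time_to_threshold(traj, metric$component, metric$level,
                        metric$direction)
    else NA_real_
    data.frame(value = v, valid = TRUE, x = fin$x, y = fin$y, z = fin$z,
               metric_time = mt)
  })
  out <- if (length(rows) == 0L)
    data.frame(value = numeric(0), valid = logical(0), x = numeric(0),
               y = numeric(0), z = numeric(0), metric_time = numeric(0))
  else do.call(rbind, rows)
  if (!is.list(metric)) out$metric_time <- NULL
  attr(out, "name") <- name
  attr(out, "metric") <- metric
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Write a trajectory to CSV
#'
#' Columns `t,x,y,z` with a header row, full floating precision.
#'
#' @param traj a `"game_trajectory"`.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  stopifnot(inherits(traj, "game_trajectory"))
  out <- data.frame(t = traj$time, x = traj$x, y = traj$y, z = traj$z)
  utils::write.csv(format(out, digits = 17, trim = TRUE), file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}
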