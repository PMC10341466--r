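#' Tripartite healthcare-fraud supervision game
#'
#' Constructs the model object for the three-player evolutionary game between
#' a hospital (compliant vs illegal operation, frequency `x`), a third-party
#' investigator (true vs false investigation, frequency `y`) and a local
#' government (strict supervision vs non-supervision, frequency `z`).
#' Strategy frequencies evolve by replicator dynamics driven by the
#' payoff-advantage factors `G`, `J`, `H` (see [replicator_rates()]).
#'
#' @inheritParams replicator_rates
#' @param params a `"game_params"` parameter set ([game_params()],
#'   [scenario_params()], [read_params()]).
#' @return Object of class `"fraud_game"` with the parameter set, dynamics
#'   mode, ESS condition flags and the corner stability report.
#' @examples
#' g <- fraud_game(scenario_params(3))
#' g
#' summary(g)
#' tr <- simulate(g)
#' tail(tr, 1)
#' @export
fraud_game <- function(params, mode = c("reference", "matrix")) {
  params <- coerce_params(params)
  mode <- check_mode(mode)
  viol <- validate_params(params, strict = TRUE)
  if (length(viol) > 0L)
    stop("invalid parameter set: ", paste(viol, collapse = "; "))
  structure(list(params = params, mode = mode,
                 flags = condition_flags(params),
                 stability = stability_report(params, mode)),
            class = "fraud_game")
}

#' @export
print.fraud_game <- function(x, ...) {
  cat("Tripartite healthcare-fraud supervision game (mode:", x$mode, ")\n")
  print(x$params)
  ess <- x$stability$point[x$stability$class == "ESS"]
  cat("ESS conditions: A =", x$flags[["A"]], " B =", x$flags[["B"]],
      " C =", x$flags[["C"]], "\n")
  cat("ESS corner(s):", if (length(ess)) paste(ess, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' @export
coef.fraud_game <- function(object, ...) unclass(object$params)

#' Summarize a supervision game
#'
#' Corner stability classification plus the threshold geometry in both the
#' triangle approximation and the numerical-integration reference.
#'
#' @param object a `"fraud_game"`.
#' @param ... unused.
#' @return List of class `"summary.fraud_game"`.
#' @export
summary.fraud_game <- function(object, ...) {
  structure(list(game = object,
                 geometry_triangle = threshold_geometry(object$params,
                                                        "triangle",
                                                        mode = object$mode),
                 geometry_integral = threshold_geometry(object$params,
                                                        "integral",
                                                        mode = object$mode)),
            class = "summary.fraud_game")
}

#' @export
print.summary.fraud_game <- function(x, ...) {
  print(x$game)
  cat("\nCorner stability:\n")
  print(x$game$stability, row.names = FALSE)
  cat("\n"); print(x$geometry_triangle)
  cat("\n"); print(x$geometry_integral)
  invisible(x)
}

#' Simulate trajectories of a supervision game
#'
#' Integrates the replicator dynamics of the game.  With `nsim = 1` the
#' supplied initial state is used; with `nsim > 1`, `nsim` initial states are
#' drawn uniformly from the open cube under `seed` and a list of
#' trajectories is returned.
#'
#' @param object a `"fraud_game"`.
#' @param nsim number of trajectories.
#' @param seed RNG seed for random initial states when `nsim > 1`.
#' @param init initial state for `nsim = 1`.
#' @param t_end integration horizon.
#' @param ... passed to [integrate_game()].
#' @return A `"game_trajectory"` (`nsim = 1`) or a list of them.
#' @export
simulate.fraud_game <- function(object, nsim = 1, seed = NULL,
                                init = c(0.8, 0.5, 0.2), t_end = 50, ...) {
  if (nsim == 1)
    return(integrate_game(object$params, init = init, t_end = t_end,
                          mode = object$mode, ...))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  starts <- matrix(stats::runif(3 * nsim, 0.02, 0.98), ncol = 3)
  lapply(seq_len(nsim), function(i)
    integrate_game(object$params, init = starts[i, ], t_end = t_end,
                   mode = object$mode, ...))
}

#' Plot a replicator trajectory
#'
#' Strategy frequencies `x` (hospital compliant), `y` (true investigation)
#' and `z` (strict supervision) against time.
#'
#' @param x a `"game_trajectory"`.
#' @param ... further arguments to [graphics::matplot()].
#' @return The trajectory, invisibly.
#' @export
plot.game_trajectory <- function(x, ...) {
  graphics::matplot(x$time, cbind(x$x, x$y, x$z), type = "l", lty = 1,
                    col = c("#1b6ca8", "#d1495b", "#66a182"),
                    xlab = "time", ylab = "strategy frequency",
                    ylim = c(0, 1), ...)
  graphics::legend("right",
                   legend = c("x (hospital compliant)",
                              "y (true investigation)",
                              "z (strict supervision)"),
                   col = c("#1b6ca8", "#d1495b", "#66a182"),
                   lty = 1, bty = "n")
  invisible(x)
}

#' @export
print.game_trajectory <- function(x, ...) {
  cat("Replicator trajectory:", nrow(x), "states on t = [0, ",
      max(x$time), "], mode ", attr(x, "mode"), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 4), row.names = FALSE)
  cat("...\n")
  print.data.frame(utils::tail(as.data.frame(x), 1), row.names = FALSE)
  invisible(x)
}
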