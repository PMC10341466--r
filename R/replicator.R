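# Replicator dynamics on the unit cube.
#
# F(x) = x(1-x) G(y,z),  F(y) = y(1-y) J(x,z),  F(z) = z(z-1) H(x,y),
# where G, J, H are the payoff-advantage factors of the hospital, the third
# party and the local government.  Two dynamics modes are supported:
#   "reference" - the equation system in the form conventionally stated for
#                 this game; its third-party factor J carries an extra
#                 bilinear term  x*z*(It1 - It2)  relative to the payoff
#                 matrix (see equation_audit()).
#   "matrix"    - the factors derived exactly from the Table of payoffs.
# G and H are identical in both modes.

dynamics_modes <- c("reference", "matrix")

check_mode <- function(mode) match.arg(mode, dynamics_modes)

check_prob <- function(v, name) {
  if (any(!is.finite(v)) || any(v < 0 | v > 1))
    stop(name, " must lie in [0, 1]")
  v
}

#' Hospital payoff-advantage factor G
#'
#' `G(y, z) = Ch2 - Ch1 + Ih1 - Ih2 + z*Ah + Ph*(y + z - y*z)`: the expected
#' payoff of compliant operation minus that of illegal operation.  The
#' hospital's replicator rate is `x (1 - x) G`.  `G` is non-decreasing in both
#' `y` and `z` (`dG/dy = Ph (1 - z) >= 0`).
#'
#' @inheritParams validate_params
#' @param y,z probabilities of a true investigation and of strict supervision;
#'   vectorized.
#' @return Numeric vector of factor values.
#' @export
G_factor <- function(params, y, z) {
  p <- as.list(coerce_params(params))
  check_prob(y, "y"); check_prob(z, "z")
  p$Ch2 - p$Ch1 + p$Ih1 - p$Ih2 + z * p$Ah + p$Ph * (y + z - y * z)
}

#' Third-party payoff-advantage factor J
#'
#' Expected payoff of a true investigation minus a false one.  In
#' `"reference"` mode
#' `J = Ct2 - Ct1 + (It1 - It2)(1 - x + x*z) + z*Pt`; in `"matrix"` mode
#' (derived from the payoff matrix)
#' `J = Ct2 - Ct1 + (1 - x)(It1 - It2) + z*Pt`.  The two differ by exactly
#' `x*z*(It1 - It2)`.
#'
#' @inheritParams G_factor
#' @param x probability of compliant hospital operation; vectorized.
#' @param mode `"reference"` (default) or `"matrix"`.
#' @return Numeric vector of factor values.
#' @export
J_factor <- function(params, x, z, mode = c("reference", "matrix")) {
  p <- as.list(coerce_params(params))
  mode <- check_mode(mode)
  check_prob(x, "x"); check_prob(z, "z")
  dI <- p$It1 - p$It2
  base <- p$Ct2 - p$Ct1 + z * p$Pt
  if (mode == "reference") base + dI * (1 - x + x * z)
  else base + dI * (1 - x)
}

#' Government payoff-advantage factor H
#'
#' `H(x, y) = Cg - Ag - Pg - Ph - Pt + x*Ah + (x + y - x*y)(Pg + Ph) + y*Pt`:
#' the expected payoff of non-supervision minus strict supervision, so the
#' government's replicator rate is `z (z - 1) H`.  Identical in both dynamics
#' modes, and non-decreasing in `x` and `y`
#' (`dH/dy = (Pg + Ph)(1 - x) + Pt > 0`).
#'
#' @inheritParams J_factor
#' @return Numeric vector of factor values.
#' @export
H_factor <- function(params, x, y) {
  p <- as.list(coerce_params(params))
  check_prob(x, "x"); check_prob(y, "y")
  p$Cg - p$Ag - p$Pg - p$Ph - p$Pt + x * p$Ah +
    (x + y - x * y) * (p$Pg + p$Ph) + y * p$Pt
}

#' Replicator vector field
#'
#' Rates of change of the mixed state under the replicator dynamics:
#' `dx/dt = x(1-x) G(y,z)`, `dy/dt = y(1-y) J(x,z)`,
#' `dz/dt = z(z-1) H(x,y)`.  Each component vanishes exactly when its own
#' coordinate sits on the boundary, so the unit cube is invariant.
#'
#' @inheritParams J_factor
#' @param state numeric triple `(x, y, z)` in the unit cube.
#' @return Named numeric vector `c(dx_dt=, dy_dt=, dz_dt=)`.
#' @examples
#' replicator_rates(scenario_params(1), c(0.8, 0.5, 0.2))
#' @export
replicator_rates <- function(params, state, mode = c("reference", "matrix")) {
  params <- coerce_params(params)
  mode <- check_mode(mode)
  s <- check_state(state)
  x <- s[["x"]]; y <- s[["y"]]; z <- s[["z"]]
  c(dx_dt = x * (1 - x) * G_factor(params, y, z),
    dy_dt = y * (1 - y) * J_factor(params, x, z, mode),
    dz_dt = z * (z - 1) * H_factor(params, x, y))
}

#' Difference between the two dynamics modes
#'
#' Describes the residual (reference minus matrix-derived) of each component
#' of the replicator field.  The `x` and `z` components agree identically;
#' the `y` component differs by `y(1-y) * x * z * (It1 - It2)`.
#'
#' @inheritParams validate_params
#' @return List with a human-readable `description` per component and a
#'   function `residual(state)` evaluating the exact closed-form difference.
#' @export
mode_residual <- function(params) {
  params <- coerce_params(params)
  dI <- params[["It1"]] - params[["It2"]]
  list(
    description = c(
      x = "0 (modes identical)",
      y = sprintf("y*(1-y)*x*z*(It1-It2) = y*(1-y)*x*z*(%g)", dI),
      z = "0 (modes identical)"),
    residual = function(state) {
      s <- check_state(state)
      c(x = 0,
        y = s[["y"]] * (1 - s[["y"]]) * s[["x"]] * s[["z"]] * dI,
        z = 0)
    })
}

# Truncated strict-supervision expected payoff: the three-term variant of E31
# that omits the (1-x)(1-y) profile.  Kept only so equation_audit() can
# quantify the omission against the matrix-derived E31.
e31_truncated <- function(params, x, y) {
  p <- as.list(coerce_params(params))
  x * y * (p$Ig1 - p$Cg - p$Ah + p$Ag) +
    x * (1 - y) * (p$Ig1 - p$Cg - p$Ah + p$Pt + p$Ag) +
    (1 - x) * y * (p$Ig2 - p$Cg + p$Ph + p$Ag)
}

#' Audit the closed-form equations against the payoff matrix
#'
#' Cross-checks the closed-form replicator equations against the field derived
#' from the payoff matrix on a deterministic grid of interior states:
#' \itemize{
#'   \item the `x` and `z` components agree identically;
#'   \item the `y` components differ by exactly `y(1-y) x z (It1 - It2)`;
#'   \item the three-term truncated variant of the strict-supervision expected
#'     payoff `E31` differs from the matrix-derived `E31` by exactly the
#'     omitted profile term `(1-x)(1-y)(Ig2 - Cg + Ph + Pt + Ag)`.
#' }
#' All expressions are polynomials of total degree at most 3, so agreement on
#' a generic grid certifies the identities.
#'
#' @inheritParams validate_params
#' @param n number of grid states per audit (default 64).
#' @return Named numeric vector of maximum absolute deviations:
#'   `x_component`, `z_component`, `y_component_minus_closed_form`,
#'   `e31_truncation_minus_closed_form`.  All are ~1e-12 or below.
#' @export
equation_audit <- function(params, n = 64) {
  params <- coerce_params(params)
  pts <- seq(0.05, 0.95, length.out = ceiling(n^(1 / 3)) + 1)
  grid <- expand.grid(x = pts, y = pts, z = pts)
  dI <- params[["It1"]] - params[["It2"]]
  p <- as.list(params)
  dev <- matrix(NA_real_, nrow(grid), 4)
  for (i in seq_len(nrow(grid))) {
    st <- as.numeric(grid[i, ])
    e <- expected_payoffs(params, st)
    ref <- replicator_rates(params, st, "reference")
    x <- st[1]; y <- st[2]; z <- st[3]
    mat <- c(x * (1 - x) * (e$E11 - e$E12),
             y * (1 - y) * (e$E21 - e$E22),
             z * (z - 1) * (e$E32 - e$E31))
    dev[i, 1] <- abs(ref[1] - mat[1])
    dev[i, 3] <- abs(ref[3] - mat[3])
    dev[i, 2] <- abs((ref[2] - mat[2]) - y * (1 - y) * x * z * dI)
    omit <- (1 - x) * (1 - y) * (p$Ig2 - p$Cg + p$Ph + p$Pt + p$Ag)
    dev[i, 4] <- abs((e$E31 - e31_truncated(params, x, y)) - omit)
  }
  out <- apply(dev, 2, max)
  names(out) <- c("x_component", "y_component_minus_closed_form",
                  "z_component", "e31_truncation_minus_closed_form")
  out
}
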