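# Equilibrium enumeration and first-Lyapunov stability classification.

corner_table <- data.frame(
  label = paste0("E", 1:8),
  x = c(0, 1, 0, 0, 1, 1, 0, 1),
  y = c(0, 0, 1, 0, 1, 0, 1, 1),
  z = c(0, 0, 0, 1, 0, 1, 1, 1),
  stringsAsFactors = FALSE)

# conventional reporting order of the three eigenvalues per corner row:
# positions into (lambda_x, lambda_y, lambda_z)
corner_eigen_order <- list(
  E1 = c(1, 2, 3), E2 = c(2, 3, 1), E3 = c(3, 2, 1), E4 = c(3, 2, 1),
  E5 = c(2, 3, 1), E6 = c(3, 2, 1), E7 = c(3, 2, 1), E8 = c(3, 2, 1))

#' The eight pure-strategy equilibrium points
#'
#' Corners of the strategy cube, labelled `E1(0,0,0)`, `E2(1,0,0)`,
#' `E3(0,1,0)`, `E4(0,0,1)`, `E5(1,1,0)`, `E6(1,0,1)`, `E7(0,1,1)`,
#' `E8(1,1,1)`.  Every corner is a rest point of the replicator field for any
#' parameter set.
#'
#' @return Data frame with columns `label`, `x`, `y`, `z`.
#' @export
pure_equilibria <- function() corner_table

#' Jacobian of the replicator field
#'
#' Analytic 3x3 Jacobian of the replicator field at a state, in the selected
#' dynamics mode.  At any corner of the cube the off-diagonal entries vanish,
#' so the eigenvalues are the diagonal entries.
#'
#' @inheritParams replicator_rates
#' @return 3x3 numeric matrix with dimnames `x`, `y`, `z`.
#' @export
jacobian_at <- function(params, state, mode = c("reference", "matrix")) {
  p <- as.list(coerce_params(params))
  mode <- check_mode(mode)
  s <- check_state(state)
  x <- s[["x"]]; y <- s[["y"]]; z <- s[["z"]]
  G <- G_factor(params, y, z)
  J <- J_factor(params, x, z, mode)
  H <- H_factor(params, x, y)
  dG_dy <- p$Ph * (1 - z)
  dG_dz <- p$Ah + p$Ph * (1 - y)
  dI <- p$It1 - p$It2
  if (mode == "reference") {
    dJ_dx <- dI * (z - 1)
    dJ_dz <- p$Pt + dI * x
  } else {
    dJ_dx <- -dI
    dJ_dz <- p$Pt
  }
  dH_dx <- p$Ah + (p$Pg + p$Ph) * (1 - y)
  dH_dy <- (p$Pg + p$Ph) * (1 - x) + p$Pt
  m <- rbind(
    c((1 - 2 * x) * G, x * (1 - x) * dG_dy, x * (1 - x) * dG_dz),
    c(y * (1 - y) * dJ_dx, (1 - 2 * y) * J, y * (1 - y) * dJ_dz),
    c(z * (z - 1) * dH_dx, z * (z - 1) * dH_dy, (2 * z - 1) * H))
  dimnames(m) <- list(c("x", "y", "z"), c("x", "y", "z"))
  m
}

resolve_corner <- function(point) {
  if (is.character(point) && length(point) == 1L) {
    i <- match(point, corner_table$label)
    if (is.na(i)) stop("unknown corner label: ", point)
    return(corner_table[i, ])
  }
  s <- as.numeric(unlist(point))[1:3]
  i <- which(corner_table$x == s[1] & corner_table$y == s[2] &
               corner_table$z == s[3])
  if (length(i) != 1L)
    stop("stability classification supports only the eight pure-strategy ",
         "corners; mixed points are out of scope")
  corner_table[i, ]
}

#' Eigenvalues at a pure-strategy equilibrium
#'
#' The Jacobian at a corner is diagonal, with entries
#' `lambda_x = (1-2x) G`, `lambda_y = (1-2y) J`, `lambda_z = (2z-1) H`
#' evaluated at the corner.  Eigenvalues are reported in the conventional
#' per-corner order (e.g. `E1`: `(lambda_x, lambda_y, lambda_z)`; `E6`:
#' `(lambda_z, lambda_y, lambda_x)`), matching the usual tabulation of this
#' model.
#'
#' @inheritParams replicator_rates
#' @param point corner label `"E1"` ... `"E8"`, or an exact corner coordinate
#'   triple.  Mixed (non-corner) points are an error.
#' @return Named numeric vector `c(lambda1=, lambda2=, lambda3=)`.
#' @examples
#' eigenvalues_at_pure(scenario_params(1), "E1")   # (-4, -2, -1)
#' @export
eigenvalues_at_pure <- function(params, point, mode = c("reference", "matrix")) {
  params <- coerce_params(params)
  mode <- check_mode(mode)
  cr <- resolve_corner(point)
  lam_xyz <- diag(jacobian_at(params, c(cr$x, cr$y, cr$z), mode))
  lam <- lam_xyz[corner_eigen_order[[cr$label]]]
  names(lam) <- c("lambda1", "lambda2", "lambda3")
  lam
}

#' Classify a pure-strategy equilibrium (first Lyapunov method)
#'
#' An equilibrium is an ESS when all three eigenvalues are below `-tol`,
#' unstable when all are above `+tol`, a saddle when the strict signs are
#' mixed, and indeterminate when any eigenvalue lies within `tol` of zero
#' (linearization is then inconclusive).
#'
#' @inheritParams eigenvalues_at_pure
#' @param tol sign tolerance for eigenvalue calls (default `1e-9`).
#' @return One of `"ESS"`, `"unstable"`, `"saddle"`, `"indeterminate"`.
#' @export
classify_equilibrium <- function(params, point, mode = c("reference", "matrix"),
                                 tol = 1e-9) {
  lam <- eigenvalues_at_pure(params, point, mode)
  if (any(abs(lam) <= tol)) return("indeterminate")
  if (all(lam < 0)) return("ESS")
  if (all(lam > 0)) return("unstable")
  "saddle"
}

#' ESS existence conditions A, B and C
#'
#' The parameter inequalities under which the three candidate stable corners
#' are evolutionarily stable:
#' \describe{
#'   \item{A}{`Cg > Ag + Pg + Ph + Pt` - supervision too costly, `E1(0,0,0)`
#'     is the ESS.}
#'   \item{B}{`Pt < Ct1 - Ct2 + It2 - It1` and
#'     `Ah + Ph < Ch1 - Ch2 + Ih2 - Ih1` - supervision pays but deterrence is
#'     too weak, `E4(0,0,1)` is the ESS.}
#'   \item{C}{`Ah + Cg < Ag + Pt` - supervision is subsidised enough that
#'     `E6(1,0,1)` (compliant operation under strict supervision) is the
#'     ESS.}
#' }
#'
#' A is exactly equivalent to `E1` being an ESS (its other two eigenvalues
#' are negative for every valid parameter set).  B and C are necessary for
#' `E4` and `E6` respectively but sufficient only together with the signs of
#' the remaining corner eigenvalues: `E4` additionally needs
#' `Cg < Ag + Pg + Ph + Pt`, and `E6` needs `Pt < Ct1 - Ct2 + It2 - It1` and
#' `Ah + Ph > Ch1 - Ch2 + Ih2 - Ih1`.  Use [classify_equilibrium()] for the
#' definitive call.
#'
#' @inheritParams validate_params
#' @return Named logical vector `c(A=, B=, C=)`.
#' @examples
#' condition_flags(scenario_params(1))   # A TRUE, B FALSE, C FALSE
#' @export
condition_flags <- function(params) {
  p <- as.list(coerce_params(params))
  c(A = p$Cg > p$Ag + p$Pg + p$Ph + p$Pt,
    B = (p$Pt < p$Ct1 - p$Ct2 + p$It2 - p$It1) &&
        (p$Ah + p$Ph < p$Ch1 - p$Ch2 + p$Ih2 - p$Ih1),
    C = p$Ah + p$Cg < p$Ag + p$Pt)
}

#' The set of ESS corners
#'
#' @inheritParams classify_equilibrium
#' @return Character vector of corner labels classified `"ESS"`; under the
#'   reference dynamics and strict valid parameters this is a subset of
#'   `{"E1", "E4", "E6"}`.
#' @export
ess_set <- function(params, mode = c("reference", "matrix"), tol = 1e-9) {
  mode <- check_mode(mode)
  labs <- corner_table$label
  labs[vapply(labs, function(l)
    classify_equilibrium(params, l, mode, tol) == "ESS", logical(1))]
}

#' Stability report over all corners
#'
#' Eigenvalues and first-Lyapunov classification of each pure-strategy
#' equilibrium, with the ESS condition flags attached.
#'
#' @inheritParams classify_equilibrium
#' @return Data frame with columns `point`, `lambda1`, `lambda2`, `lambda3`,
#'   `class`, `condA`, `condB`, `condC`; attribute `flags` holds the raw
#'   condition flags.
#' @examples
#' stability_report(scenario_params(3))
#' @export
stability_report <- function(params, mode = c("reference", "matrix"),
                             tol = 1e-9) {
  params <- coerce_params(params)
  mode <- check_mode(mode)
  fl <- condition_flags(params)
  rows <- lapply(corner_table$label, function(l) {
    lam <- eigenvalues_at_pure(params, l, mode)
    data.frame(point = l, lambda1 = lam[[1]], lambda2 = lam[[2]],
               lambda3 = lam[[3]],
               class = classify_equilibrium(params, l, mode, tol))
  })
  out <- do.call(rbind, rows)
  out$condA <- fl[["A"]]; out$condB <- fl[["B"]]; out$condC <- fl[["C"]]
  attr(out, "flags") <- fl
  out
}

# Solve the affine equation f(v) = 0 for one factor restricted to a face,
# where fun(v) must be affine in v.  Returns list(value=, reason=).
solve_affine <- function(fun, tol = 1e-12) {
  a <- fun(0)
  b <- fun(1) - a
  if (abs(b) < tol) {
    if (abs(a) < tol)
      list(value = NA_real_, reason = "degenerate: factor vanishes identically on this face")
    else
      list(value = NA_real_, reason = "no solution: factor is constant and nonzero on this face")
  } else {
    list(value = -a / b, reason = NA_character_)
  }
}

# Unrestricted factor evaluations (arguments outside [0,1] allowed) used for
# candidate solves.
G_raw <- function(p, y, z)
  p$Ch2 - p$Ch1 + p$Ih1 - p$Ih2 + z * p$Ah + p$Ph * (y + z - y * z)
J_raw <- function(p, x, z, mode) {
  dI <- p$It1 - p$It2
  base <- p$Ct2 - p$Ct1 + z * p$Pt
  if (mode == "reference") base + dI * (1 - x + x * z) else base + dI * (1 - x)
}
H_raw <- function(p, x, y)
  p$Cg - p$Ag - p$Pg - p$Ph - p$Pt + x * p$Ah +
    (x + y - x * y) * (p$Pg + p$Ph) + y * p$Pt

#' Enumerate the 15 stationary-point candidates
#'
#' The replicator system has 15 equilibrium candidates: the 8 cube corners,
#' one candidate per cube face (the two surviving factor equations solved
#' with the third coordinate fixed at 0 or 1), and one interior candidate
#' (`G = J = H = 0`).  Face and interior candidates are solved symbolically
#' (the factors are affine on a face) or, for the interior point, by a 1-D
#' root search after eliminating `x` and `y`; coordinates falling outside
#' `[0, 1]` are flagged out-of-domain rather than dropped, and degenerate
#' solves (a factor constant on its face, as happens on the `z = 1` face)
#' are marked `"undefined"` with a reason.
#'
#' @inheritParams replicator_rates
#' @return Data frame with 15 rows: `label` (`E1`-`E8`, `A9`-`A15`), `type`
#'   (`corner`, `face`, `interior`), `face`, `x`, `y`, `z`, `in_domain`,
#'   `defined`, `reason`.
#' @examples
#' candidate_equilibria(scenario_params(1))
#' @export
candidate_equilibria <- function(params, mode = c("reference", "matrix")) {
  p <- as.list(coerce_params(params))
  mode <- check_mode(mode)
  rows <- cbind(corner_table, type = "corner", face = NA_character_,
                defined = TRUE, reason = NA_character_)

  face_specs <- list(
    A9  = list(face = "x=0", fix = c(x = 0)),
    A10 = list(face = "x=1", fix = c(x = 1)),
    A11 = list(face = "y=0", fix = c(y = 0)),
    A12 = list(face = "y=1", fix = c(y = 1)),
    A13 = list(face = "z=0", fix = c(z = 0)),
    A14 = list(face = "z=1", fix = c(z = 1)))
  face_rows <- lapply(names(face_specs), function(lab) {
    spec <- face_specs[[lab]]
    fixed <- spec$fix
    coord <- c(x = NA_real_, y = NA_real_, z = NA_real_)
    coord[names(fixed)] <- fixed
    reasons <- character(0)
    if (names(fixed) == "x") {
      sz <- solve_affine(function(v) J_raw(p, fixed[["x"]], v, mode))
      sy <- solve_affine(function(v) H_raw(p, fixed[["x"]], v))
      coord["z"] <- sz$value; coord["y"] <- sy$value
      reasons <- stats::na.omit(c(sz$reason, sy$reason))
    } else if (names(fixed) == "y") {
      sz <- solve_affine(function(v) G_raw(p, fixed[["y"]], v))
      sx <- solve_affine(function(v) H_raw(p, v, fixed[["y"]]))
      coord["z"] <- sz$value; coord["x"] <- sx$value
      reasons <- stats::na.omit(c(sz$reason, sx$reason))
    } else {
      sy <- solve_affine(function(v) G_raw(p, v, fixed[["z"]]))
      sx <- solve_affine(function(v) J_raw(p, v, fixed[["z"]], mode))
      coord["y"] <- sy$value; coord["x"] <- sx$value
      reasons <- stats::na.omit(c(sy$reason, sx$reason))
    }
    data.frame(label = lab, x = coord[["x"]], y = coord[["y"]],
               z = coord[["z"]], type = "face", face = spec$face,
               defined = length(reasons) == 0L,
               reason = if (length(reasons)) paste(reasons, collapse = "; ")
                        else NA_character_)
  })
  rows <- rbind(rows, do.call(rbind, face_rows))

  rows <- rbind(rows, interior_candidate(p, mode))
  rows$in_domain <- rows$defined &
    !is.na(rows$x) & !is.na(rows$y) & !is.na(rows$z) &
    rows$x >= 0 & rows$x <= 1 & rows$y >= 0 & rows$y <= 1 &
    rows$z >= 0 & rows$z <= 1
  rownames(rows) <- NULL
  rows[, c("label", "type", "face", "x", "y", "z", "in_domain", "defined",
           "reason")]
}

# Interior candidate: eliminate y and x via the indifference thresholds
# (G(y,z)=0 gives y(z); J(x,z)=0 gives x(z)), then search H(x(z), y(z)) = 0
# for a root in z.  Roots inside [0,1] are preferred; otherwise the root
# closest to the cube is reported and flagged out-of-domain.
interior_candidate <- function(p, mode) {
  y_of_z <- function(z)
    (p$Ch2 - p$Ch1 + p$Ih1 - p$Ih2 + z * (p$Ah + p$Ph)) / (p$Ph * (z - 1))
  x_of_z <- function(z) {
    dI <- p$It1 - p$It2
    if (mode == "reference") (p$Ct2 - p$Ct1 + dI + z * p$Pt) / (dI * (1 - z))
    else 1 + (p$Ct1 - p$Ct2 - z * p$Pt) / (p$It2 - p$It1)
  }
  h_of_z <- function(z) H_raw(p, x_of_z(z), y_of_z(z))
  zs <- setdiff(seq(-4, 4, by = 0.002), 1)
  zs <- zs[abs(zs - 1) > 1e-3]
  hv <- vapply(zs, h_of_z, numeric(1))
  ok <- is.finite(hv)
  zs <- zs[ok]; hv <- hv[ok]
  flips <- which(hv[-1] * hv[-length(hv)] < 0 &
                   abs(diff(zs)) < 0.004)  # skip the gap across z = 1
  roots <- numeric(0)
  for (i in flips) {
    r <- tryCatch(stats::uniroot(h_of_z, c(zs[i], zs[i + 1]),
                                 tol = 1e-12)$root,
                  error = function(e) NA_real_)
    if (is.finite(r)) roots <- c(roots, r)
  }
  if (length(roots) == 0L) {
    return(data.frame(label = "A15", x = NA_real_, y = NA_real_, z = NA_real_,
                      type = "interior", face = NA_character_, defined = FALSE,
                      reason = "no real solution of G=J=H=0 found in search window"))
  }
  dist_to_cube <- function(z) {
    st <- c(x_of_z(z), y_of_z(z), z)
    sqrt(sum((st - pmin(pmax(st, 0), 1))^2))
  }
  z0 <- roots[which.min(vapply(roots, dist_to_cube, numeric(1)))]
  data.frame(label = "A15", x = x_of_z(z0), y = y_of_z(z0), z = z0,
             type = "interior", face = NA_character_, defined = TRUE,
             reason = NA_character_)
}
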