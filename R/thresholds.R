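# Indifference thresholds and the region-measure geometry.
#
# On each player's own face of the cube the sign of its factor function
# decides the stable pure strategy; the factor's zero set is an indifference
# curve.  y_star (hospital), x_star (third party) and y_double_star
# (government) are those curves; their axis intercepts bound the triangle
# approximations of the region measures Vh, Vt, Vg.

#' Hospital indifference threshold y*(z)
#'
#' The probability of a true investigation at which the hospital is
#' indifferent: `G(y*(z), z) = 0`, with
#' `y*(z) = (Ch2 - Ch1 + Ih1 - Ih2 + z(Ah + Ph)) / (Ph (z - 1))`.
#' Below `y*` the hospital drifts to illegal operation (`x -> 0`); above it,
#' to compliance (`x -> 1`).
#'
#' @inheritParams validate_params
#' @param z probability of strict supervision, in `[0, 1)`; vectorized.
#' @return Numeric vector of threshold values (may lie outside `[0, 1]`).
#' @export
y_star <- function(params, z) {
  p <- as.list(coerce_params(params))
  check_prob(z, "z")
  if (any(abs(1 - z) < 1e-12))
    stop("y* is undefined at z = 1 (denominator Ph*(z-1) vanishes)")
  (p$Ch2 - p$Ch1 + p$Ih1 - p$Ih2 + z * (p$Ah + p$Ph)) / (p$Ph * (z - 1))
}

#' Third-party indifference threshold x*(z)
#'
#' The probability of compliant hospital operation at which the third party
#' is indifferent: `J(x*(z), z, mode) = 0`.  In `"reference"` mode
#' `x*(z) = (Ct2 - Ct1 + It1 - It2 + z Pt) / ((It1 - It2)(1 - z))`
#' (undefined at `z = 1`); in `"matrix"` mode
#' `x*(z) = 1 + (Ct1 - Ct2 - z Pt) / (It2 - It1)`.
#' Below `x*` the third party drifts to false investigation (`y -> 0`).
#'
#' @inheritParams J_factor
#' @return Numeric vector of threshold values (may lie outside `[0, 1]`).
#' @export
x_star <- function(params, z, mode = c("reference", "matrix")) {
  p <- as.list(coerce_params(params))
  mode <- check_mode(mode)
  check_prob(z, "z")
  dI <- p$It1 - p$It2
  if (mode == "reference") {
    if (any(abs(1 - z) < 1e-12))
      stop("x* is undefined at z = 1 in reference mode")
    (p$Ct2 - p$Ct1 + dI + z * p$Pt) / (dI * (1 - z))
  } else {
    1 + (p$Ct1 - p$Ct2 - z * p$Pt) / (p$It2 - p$It1)
  }
}

#' Government indifference threshold y**(x)
#'
#' The probability of a true investigation at which the government is
#' indifferent: `H(x, y**(x)) = 0`, with
#' `y**(x) = (Ag - Cg + Pg + Ph + Pt - x(Ah + Pg + Ph)) /
#'           (Pg + Ph + Pt - x(Pg + Ph))`.
#' The denominator `(Pg + Ph)(1 - x) + Pt` is strictly positive for valid
#' strict parameters.  Below `y**` strict supervision is stable (`z -> 1`);
#' above it the government drifts to non-supervision.
#'
#' @inheritParams J_factor
#' @param x probability of compliant operation, in `[0, 1]`; vectorized.
#' @return Numeric vector of threshold values (may lie outside `[0, 1]`).
#' @export
y_double_star <- function(params, x) {
  p <- as.list(coerce_params(params))
  check_prob(x, "x")
  num <- p$Ag - p$Cg + p$Pg + p$Ph + p$Pt - x * (p$Ah + p$Pg + p$Ph)
  den <- p$Pg + p$Ph + p$Pt - x * (p$Pg + p$Ph)
  if (any(den <= 0))
    stop("y** undefined: denominator (Pg+Ph)(1-x)+Pt must be positive")
  num / den
}

#' Threshold geometry: intercepts, segment lengths and region measures
#'
#' Computes the axis intercepts of the three indifference curves
#' (`B1`, `C1` for `y*`; `B2`, `C2` for `x*`; `B3`, `C3` for `y**`), the
#' associated segment lengths `A1B1 ... A3C3` and the region measures: `Vh2`
#' (illegal-operation basin on the hospital's `(y, z)` face), `Vt2`
#' (false-investigation basin on `(x, z)`), `Vg1` (strict-supervision basin
#' on `(x, y)`), plus complements `Vh1`, `Vt1`, `Vg2`.
#'
#' Two methods:
#' \describe{
#'   \item{`"triangle"`}{the right-triangle approximation
#'     `S = lenB * lenC / 2` from the segment formulas
#'     `A1B1 = (Ch1-Ch2-Ih1+Ih2)/(Ah+Ph)`, `A1C1 = (Ch1-Ch2-Ih1+Ih2)/Ph`,
#'     `A2B2 = (Ct1-Ct2-It1+It2)/Pt`, `A2C2 = (Ct1-Ct2-It1+It2)/(It2-It1)`,
#'     `A3B3 = (Ag-Cg+Pg+Ph+Pt)/(Ah+Pg+Ph)`,
#'     `A3C3 = (Ag-Cg+Pg+Ph+Pt)/(Pg+Ph+Pt)`.  The curves are hyperbolic and
#'     the intercepts can exceed 1, so results are clipped to `[0, 1]`
#'     (`clipped` flags say where); non-positive government intercepts give
#'     an empty strict-supervision region (`Vg1 = 0`).}
#'   \item{`"integral"`}{midpoint-rule measure of the exact sign regions
#'     `{G < 0}`, `{J < 0}`, `{H < 0}` on an `n x n` grid of the unit
#'     square.}
#' }
#'
#' @inheritParams J_factor
#' @param method `"triangle"` or `"integral"`.
#' @param n grid resolution per axis for the integral method (default 512).
#' @return List of class `"threshold_geometry"`: intercepts, segment lengths,
#'   `S1`, `S2`, `S3`, the six region measures, `clipped` flags and the
#'   method tag.
#' @examples
#' threshold_geometry(scenario_params(2))
#' threshold_geometry(scenario_params(1), method = "integral")
#' @export
threshold_geometry <- function(params, method = c("triangle", "integral"),
                               n = 512, mode = c("reference", "matrix")) {
  params <- coerce_params(params)
  method <- match.arg(method)
  mode <- check_mode(mode)
  viol <- validate_params(params, strict = TRUE)
  if (length(viol) > 0L)
    stop("threshold geometry undefined for non-strict parameters: ",
         paste(viol, collapse = "; "))
  p <- as.list(params)
  K1 <- p$Ch1 - p$Ch2 - p$Ih1 + p$Ih2
  K2 <- p$Ct1 - p$Ct2 - p$It1 + p$It2
  K3 <- p$Ag - p$Cg + p$Pg + p$Ph + p$Pt
  seg <- c(A1B1 = K1 / (p$Ah + p$Ph), A1C1 = K1 / p$Ph,
           A2B2 = K2 / p$Pt,          A2C2 = K2 / (p$It2 - p$It1),
           A3B3 = K3 / (p$Ah + p$Pg + p$Ph), A3C3 = K3 / (p$Pg + p$Ph + p$Pt))
  intercepts <- c(B1 = K1 / p$Ph, C1 = K1 / (p$Ah + p$Ph),
                  B2 = K2 / p$Pt, C2 = K2 / (p$It2 - p$It1),
                  B3 = K3 / (p$Ah + p$Pg + p$Ph), C3 = K3 / (p$Pg + p$Ph + p$Pt))
  clip01 <- function(v) pmin(pmax(v, 0), 1)

  if (method == "triangle") {
    S1 <- seg[["A1B1"]] * seg[["A1C1"]] / 2
    S2 <- seg[["A2B2"]] * seg[["A2C2"]] / 2
    S3 <- if (seg[["A3B3"]] > 0 && seg[["A3C3"]] > 0)
      seg[["A3B3"]] * seg[["A3C3"]] / 2 else 0
    Vh2 <- clip01(S1); Vt2 <- clip01(S2); Vg1 <- clip01(S3)
    clipped <- c(
      Vh2 = S1 != Vh2 || any(seg[c("A1B1", "A1C1")] > 1),
      Vt2 = S2 != Vt2 || any(seg[c("A2B2", "A2C2")] > 1),
      Vg1 = (K3 > 0 && S3 != Vg1) || any(seg[c("A3B3", "A3C3")] > 1) ||
        K3 <= 0)
  } else {
    mid <- (seq_len(n) - 0.5) / n
    u <- rep(mid, times = n); v <- rep(mid, each = n)
    S1 <- mean(G_factor(params, u, v) < 0)               # (y, z) face
    S2 <- mean(J_factor(params, u, v, mode) < 0)          # (x, z) face
    S3 <- mean(H_factor(params, u, v) < 0)                # (x, y) face
    Vh2 <- S1; Vt2 <- S2; Vg1 <- S3
    clipped <- c(Vh2 = FALSE, Vt2 = FALSE, Vg1 = FALSE)
  }
  structure(list(
    intercepts = intercepts, segments = seg,
    S1 = S1, S2 = S2, S3 = S3,
    measures = c(Vh1 = 1 - Vh2, Vh2 = Vh2, Vt1 = 1 - Vt2, Vt2 = Vt2,
                 Vg1 = Vg1, Vg2 = 1 - Vg1),
    clipped = clipped, method = method, mode = mode, n = if (method == "integral") n),
    class = "threshold_geometry")
}

#' @export
print.threshold_geometry <- function(x, digits = 4, ...) {
  cat("Threshold geometry (", x$method, " method)\n", sep = "")
  cat("intercepts:\n"); print(round(x$intercepts, digits))
  cat("segment lengths:\n"); print(round(x$segments, digits))
  cat("region measures:\n"); print(round(x$measures, digits))
  if (any(x$clipped))
    cat("clipped to [0,1]:", paste(names(x$clipped)[x$clipped], collapse = ", "),
        "\n")
  invisible(x)
}

# closed-form partial derivatives of the six segment lengths
segment_derivatives <- function(params) {
  p <- as.list(coerce_params(params))
  K1 <- p$Ch1 - p$Ch2 - p$Ih1 + p$Ih2
  K2 <- p$Ct1 - p$Ct2 - p$It1 + p$It2
  K3 <- p$Ag - p$Cg + p$Pg + p$Ph + p$Pt
  d1 <- p$Ah + p$Ph; d2 <- p$It2 - p$It1
  d3 <- p$Ah + p$Pg + p$Ph; d4 <- p$Pg + p$Ph + p$Pt
  rows <- list(
    A1B1 = c(Ch1 = 1 / d1, Ch2 = -1 / d1, Ih1 = -1 / d1, Ih2 = 1 / d1,
             Ah = -K1 / d1^2, Ph = -K1 / d1^2),
    A1C1 = c(Ch1 = 1 / p$Ph, Ch2 = -1 / p$Ph, Ih1 = -1 / p$Ph,
             Ih2 = 1 / p$Ph, Ah = 0, Ph = -K1 / p$Ph^2),
    A2B2 = c(Ct1 = 1 / p$Pt, Ct2 = -1 / p$Pt, It1 = -1 / p$Pt,
             It2 = 1 / p$Pt, Pt = -K2 / p$Pt^2),
    A2C2 = c(Ct1 = 1 / d2, Ct2 = -1 / d2, It1 = (p$Ct1 - p$Ct2) / d2^2,
             It2 = -(p$Ct1 - p$Ct2) / d2^2, Pt = 0),
    A3B3 = c(Ag = 1 / d3, Cg = -1 / d3, Pt = 1 / d3, Ah = -K3 / d3^2,
             Pg = (d3 - K3) / d3^2, Ph = (d3 - K3) / d3^2),
    A3C3 = c(Ag = 1 / d4, Cg = -1 / d4, Ah = 0,
             Pg = (d4 - K3) / d4^2, Ph = (d4 - K3) / d4^2,
             Pt = (d4 - K3) / d4^2))
  rows
}

#' Sensitivity signs of segment lengths and region measures
#'
#' Closed-form partial derivatives of the six intercept segment lengths with
#' respect to each parameter entering them, cross-checked against central
#' finite differences, plus the induced signs on the region measures: `Vh2`
#' co-varies with `A1B1` (and `Vh1` oppositely), `Vt2` with `A2B2`, `Vg1`
#' with `A3B3`.  Larger rewards/fines on the hospital shrink its
#' illegal-operation basin; a larger fine on the third party shrinks its
#' false-investigation basin; superior-government rewards and fines enlarge
#' the strict-supervision basin while supervision cost and the hospital
#' reward shrink it.
#'
#' @inheritParams validate_params
#' @param fd_step relative step for the finite-difference cross-check.
#' @return Data frame with columns `quantity`, `parameter`, `derivative`
#'   (closed form), `fd` (finite difference), `sign` (`"+"`, `"-"`, `"0"`).
#'   Segment rows come first, then the induced `Vh1`, `Vh2`, `Vt1`, `Vt2`,
#'   `Vg1`, `Vg2` rows.
#' @export
sensitivity_signs <- function(params, fd_step = 1e-6) {
  params <- coerce_params(params)
  ders <- segment_derivatives(params)
  seg_value <- function(p, what) {
    g <- threshold_geometry(p, method = "triangle")
    g$segments[[what]]
  }
  out <- list()
  for (what in names(ders)) {
    for (nm in names(ders[[what]])) {
      d <- ders[[what]][[nm]]
      h <- fd_step * max(1, abs(params[[nm]]))
      up <- params; up[nm] <- up[nm] + h
      dn <- params; dn[nm] <- dn[nm] - h
      fd <- (seg_value(up, what) - seg_value(dn, what)) / (2 * h)
      out[[length(out) + 1L]] <- data.frame(
        quantity = what, parameter = nm, derivative = d, fd = fd,
        sign = if (abs(d) < 1e-12) "0" else if (d > 0) "+" else "-")
    }
  }
  seg_tab <- do.call(rbind, out)
  flip <- function(s) chartr("+-", "-+", s)
  induced <- function(region, from, flip_sign = FALSE) {
    rows <- seg_tab[seg_tab$quantity == from, ]
    rows$quantity <- region
    rows$derivative <- if (flip_sign) -rows$derivative else rows$derivative
    rows$fd <- if (flip_sign) -rows$fd else rows$fd
    rows$sign <- if (flip_sign) flip(rows$sign) else rows$sign
    rows
  }
  rbind(seg_tab,
        induced("Vh2", "A1B1"), induced("Vh1", "A1B1", TRUE),
        induced("Vt2", "A2B2"), induced("Vt1", "A2B2", TRUE),
        induced("Vg1", "A3B3"), induced("Vg2", "A3B3", TRUE))
}
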