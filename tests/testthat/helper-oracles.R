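# Independent oracles used across tests.

# Closed-form corner eigenvalue rows, transcribed directly from the standard
# tabulation of this game (independent of the package's Jacobian route).
corner_eigen_oracle <- function(p, label) {
  p <- as.list(p)
  with(p, switch(label,
    E1 = c(Ch2 - Ch1 + Ih1 - Ih2, Ct2 - Ct1 + It1 - It2,
           Ag - Cg + Pg + Ph + Pt),
    E2 = c(Ct2 - Ct1, Ag - Ah - Cg + Pt, Ch1 - Ch2 - Ih1 + Ih2),
    E3 = c(Ag - Cg, Ct1 - Ct2 - It1 + It2, Ch2 - Ch1 + Ih1 - Ih2 + Ph),
    E4 = c(Cg - Ag - Pg - Ph - Pt, Ct2 - Ct1 + It1 - It2 + Pt,
           Ah - Ch1 + Ch2 + Ih1 - Ih2 + Ph),
    E5 = c(Ct1 - Ct2, Ag - Ah - Cg, Ch1 - Ch2 - Ih1 + Ih2 - Ph),
    E6 = c(Ah - Ag + Cg - Pt, Ct2 - Ct1 + It1 - It2 + Pt,
           Ch1 - Ah - Ch2 - Ih1 + Ih2 - Ph),
    E7 = c(Cg - Ag, Ct1 - Ct2 - It1 + It2 - Pt,
           Ah - Ch1 + Ch2 + Ih1 - Ih2 + Ph),
    E8 = c(Ah - Ag + Cg, Ct1 - Ct2 - It1 + It2 - Pt,
           Ch1 - Ah - Ch2 - Ih1 + Ih2 - Ph)))
}

# Central finite-difference Jacobian of the replicator field.
fd_jacobian <- function(params, state, mode = "reference", h = 1e-6) {
  m <- matrix(NA_real_, 3, 3)
  for (j in 1:3) {
    up <- state; dn <- state
    up[j] <- min(1, state[j] + h); dn[j] <- max(0, state[j] - h)
    m[, j] <- (replicator_rates(params, up, mode) -
                 replicator_rates(params, dn, mode)) / (up[j] - dn[j])
  }
  m
}

# Distance of a state to the nearest corner, plus that corner's label.
nearest_corner <- function(state) {
  corners <- pure_equilibria()
  d <- apply(corners[, c("x", "y", "z")], 1,
             function(cc) max(abs(cc - state)))
  k <- which.min(d)
  list(label = corners$label[k], dist = d[k])
}

scn <- lapply(1:3, scenario_params)
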