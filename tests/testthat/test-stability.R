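test_that("the eight pure equilibria are the cube corners in standard order", {
  pe <- pure_equilibria()
  expect_equal(nrow(pe), 8)
  expect_equal(pe$label, paste0("E", 1:8))
  expect_equal(unlist(pe[pe$label == "E1", c("x", "y", "z")]),
               c(x = 0, y = 0, z = 0))
  expect_equal(unlist(pe[pe$label == "E6", c("x", "y", "z")]),
               c(x = 1, y = 0, z = 1))
})

test_that("the Jacobian is diagonal at corners and matches finite differences", {
  for (s in 1:20) {
    p <- sample_valid_params(500 + s)
    st <- stats::runif(3, 0.05, 0.95)
    for (mode in c("reference", "matrix")) {
      J <- jacobian_at(p, st, mode)
      Jfd <- fd_jacobian(p, st, mode)
      expect_equal(J, Jfd, tolerance = 1e-6, ignore_attr = TRUE)
    }
    corner <- unlist(pure_equilibria()[sample.int(8, 1), c("x", "y", "z")])
    Jc <- jacobian_at(p, corner)
    expect_equal(Jc[row(Jc) != col(Jc)], rep(0, 6))
  }
  expect_equal(diag(jacobian_at(scn[[1]], c(0, 0, 0))), c(x = -4, y = -2, z = -1))
})

test_that("corner eigenvalues match the closed-form rows", {
  # scenario spot values
  expect_equal(unname(eigenvalues_at_pure(scn[[1]], "E1")), c(-4, -2, -1))
  expect_equal(unname(eigenvalues_at_pure(scn[[2]], "E4")), c(-2.8, -1, -0.2))
  expect_equal(unname(eigenvalues_at_pure(scn[[3]], "E6")), c(-0.5, -0.3, -3.1))
  # symbolic fidelity across random games, all corners
  for (s in 1:200) {
    p <- sample_valid_params(600 + s)
    for (lab in paste0("E", 1:8)) {
      expect_equal(unname(eigenvalues_at_pure(p, lab)),
                   corner_eigen_oracle(p, lab), tolerance = 1e-12)
      # numeric-Jacobian route agrees with the closed forms
      cr <- pure_equilibria()[pure_equilibria()$label == lab, ]
      lam_num <- sort(eigen(jacobian_at(p, unlist(cr[c("x", "y", "z")])),
                            only.values = TRUE)$values)
      expect_equal(lam_num, sort(corner_eigen_oracle(p, lab)),
                   tolerance = 1e-9)
    }
  }
  expect_error(eigenvalues_at_pure(scn[[1]], c(0.5, 0.5, 0.5)), "corner")
})

test_that("classification follows eigenvalue signs and the scenario claims", {
  expect_equal(classify_equilibrium(scn[[1]], "E1"), "ESS")
  # E7 in scenario 1 has lambda1 = Cg - Ag = 7 > 0 (never ESS) but its third
  # eigenvalue ties at zero (Ah + Ph = Ch1 - Ch2 + Ih2 - Ih1), so the class
  # is indeterminate rather than a guessed saddle
  expect_gt(eigenvalues_at_pure(scn[[1]], "E7")[["lambda1"]], 0)
  expect_false(classify_equilibrium(scn[[1]], "E7") == "ESS")
  expect_equal(classify_equilibrium(scn[[2]], "E7"), "saddle")
  expect_equal(ess_set(scn[[1]]), "E1")
  expect_equal(ess_set(scn[[2]]), "E4")
  expect_equal(ess_set(scn[[3]]), "E6")
  # boundary tie -> indeterminate
  p <- unclass(scn[[1]]); p["Cg"] <- 8   # Cg = Ag+Pg+Ph+Pt exactly
  expect_equal(classify_equilibrium(game_params_vec(p), "E1"), "indeterminate")
})

test_that("E2, E3, E5, E7, E8 are never an ESS for valid strict parameters", {
  for (s in 1:200) {
    p <- sample_valid_params(800 + s)
    for (lab in c("E2", "E3", "E5", "E7", "E8"))
      expect_false(classify_equilibrium(p, lab) == "ESS")
  }
})

test_that("ESS classification matches the condition-flag algebra", {
  # A is exactly equivalent to ESS(E1); B and C are necessary for E4 and E6
  # and become sufficient together with the remaining tabulated eigenvalue
  # signs (lambda1 of E4, lambda2 and lambda3 of E6)
  for (s in 1:200) {
    p <- sample_valid_params(1200 + s)
    pl <- as.list(p)
    fl <- condition_flags(p)
    e4_extra <- with(pl, Cg < Ag + Pg + Ph + Pt)
    e6_extra <- with(pl, Pt < Ct1 - Ct2 + It2 - It1 &&
                       Ah + Ph > Ch1 - Ch2 + Ih2 - Ih1)
    expect_equal(classify_equilibrium(p, "E1") == "ESS", unname(fl["A"]))
    expect_equal(classify_equilibrium(p, "E4") == "ESS",
                 unname(fl["B"]) && e4_extra)
    expect_equal(classify_equilibrium(p, "E6") == "ESS",
                 unname(fl["C"]) && e6_extra)
    if (classify_equilibrium(p, "E4") == "ESS") expect_true(unname(fl["B"]))
    if (classify_equilibrium(p, "E6") == "ESS") expect_true(unname(fl["C"]))
  }
  expect_equal(unname(condition_flags(scn[[1]])), c(TRUE, FALSE, FALSE))
  expect_equal(unname(condition_flags(scn[[2]])), c(FALSE, TRUE, FALSE))
  expect_equal(unname(condition_flags(scn[[3]])), c(FALSE, FALSE, TRUE))
})

test_that("candidate enumeration returns 15 labelled candidates", {
  ce <- candidate_equilibria(scn[[1]])
  expect_equal(nrow(ce), 15)
  expect_equal(sum(ce$type == "corner"), 8)
  expect_equal(sum(ce$type == "face"), 6)
  expect_equal(sum(ce$type == "interior"), 1)
  expect_true(all(ce$in_domain[ce$type == "corner"]))
  # the z = 0 face candidate solves G(y,0)=0, J(x,0)=0 at (2, 2): outside
  a13 <- ce[ce$label == "A13", ]
  expect_equal(c(a13$x, a13$y), c(2, 2))
  expect_false(a13$in_domain)
  # the z = 1 face is degenerate (factors constant there)
  expect_false(ce$defined[ce$label == "A14"])
  # in-domain face/interior candidates (when defined) are genuine rest points
  for (s in 1:20) {
    p <- sample_valid_params(1400 + s)
    cc <- candidate_equilibria(p)
    ok <- cc$defined & cc$in_domain
    for (i in which(ok))
      expect_equal(max(abs(replicator_rates(
        p, unlist(cc[i, c("x", "y", "z")])))), 0, tolerance = 1e-8)
  }
})

test_that("stability report carries eigenvalues, classes and flags", {
  rep1 <- stability_report(scn[[3]])
  expect_equal(nrow(rep1), 8)
  expect_equal(rep1$class[rep1$point == "E6"], "ESS")
  expect_true(all(rep1$condC))
  expect_equal(attr(rep1, "flags")[["C"]], TRUE)
})
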