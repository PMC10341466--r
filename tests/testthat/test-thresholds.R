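test_that("threshold functions match their intercept formulas", {
  p1 <- scn[[1]]
  expect_equal(y_star(p1, 0), 2)      # (Ch1-Ch2-Ih1+Ih2)/Ph
  expect_equal(x_star(p1, 0), 2)      # (Ct1-Ct2-It1+It2)/(It2-It1)
  expect_equal(y_double_star(scn[[2]], 0), 2.8 / 6.3, tolerance = 1e-12)
  expect_equal(y_double_star(p1, 0), -1 / 6, tolerance = 1e-12)
  expect_error(y_star(p1, 1), "z = 1")
  expect_error(x_star(p1, 1, "reference"), "z = 1")
  for (s in 1:50) {
    p <- sample_valid_params(1600 + s)
    pl <- as.list(p)
    expect_equal(y_star(p, 0),
                 with(pl, (Ch1 - Ch2 - Ih1 + Ih2) / Ph), tolerance = 1e-12)
    # x*(z) = 0 exactly at z = (Ct1-Ct2-It1+It2)/Pt when that z is a probability
    z0 <- with(pl, (Ct1 - Ct2 - It1 + It2) / Pt)
    if (z0 >= 0 && z0 < 1)
      expect_equal(x_star(p, z0), 0, tolerance = 1e-10)
  }
})

test_that("each threshold zeroes its factor on the domain", {
  zs <- seq(0, 0.99, length.out = 100)
  for (s in 1:20) {
    p <- sample_valid_params(1700 + s)
    for (z in zs) {
      ys <- y_star(p, z)
      if (ys >= 0 && ys <= 1)
        expect_equal(G_factor(p, ys, z), 0, tolerance = 1e-10)
      for (mode in c("reference", "matrix")) {
        xs <- x_star(p, z, mode)
        if (xs >= 0 && xs <= 1)
          expect_equal(J_factor(p, xs, z, mode), 0, tolerance = 1e-10)
      }
    }
    for (x in seq(0, 1, length.out = 50)) {
      yd <- y_double_star(p, x)
      if (yd >= 0 && yd <= 1)
        expect_equal(H_factor(p, x, yd), 0, tolerance = 1e-10)
    }
  }
})

test_that("triangle geometry reproduces the scenario values", {
  g1 <- threshold_geometry(scn[[1]], "triangle")
  expect_equal(unname(g1$segments[c("A1B1", "A1C1")]), c(1, 2))
  expect_equal(unname(g1$measures["Vh2"]), 1)   # S1 = 1, clipped region
  expect_true(g1$clipped[["Vh2"]])
  expect_equal(unname(g1$measures["Vg1"]), 0)   # negative intercepts: empty
  g2 <- threshold_geometry(scn[[2]], "triangle")
  expect_equal(unname(g2$measures["Vg1"]), 0.5 * (2.8 / 7.8) * (2.8 / 6.3),
               tolerance = 1e-12)
  # geometry requires strictly positive fines
  p <- unclass(scn[[1]]); p["Pt"] <- 0
  expect_error(threshold_geometry(game_params_vec(p, validate = FALSE)),
               "Pt>0")
})

test_that("integral geometry measures the exact sign regions", {
  g1 <- threshold_geometry(scn[[1]], "integral")
  expect_equal(unname(g1$measures["Vg1"]), 0)   # H > 0 on the whole square
  for (s in 1:25) {
    p <- sample_valid_params(1800 + s)
    for (method in c("triangle", "integral")) {
      m <- threshold_geometry(p, method, n = 128)$measures
      expect_equal(unname(m["Vh1"] + m["Vh2"]), 1)
      expect_equal(unname(m["Vt1"] + m["Vt2"]), 1)
      expect_equal(unname(m["Vg1"] + m["Vg2"]), 1)
      expect_true(all(m >= 0 & m <= 1))
    }
  }
  # grid refinement has settled at the default resolution
  a <- threshold_geometry(scn[[2]], "integral", n = 256)$measures
  b <- threshold_geometry(scn[[2]], "integral", n = 512)$measures
  expect_equal(a, b, tolerance = 2e-3)
})

test_that("closed-form sensitivity signs agree with finite differences", {
  for (s in c(3, 21, 77)) {
    p <- sample_valid_params(s)
    tab <- sensitivity_signs(p)
    expect_equal(tab$derivative, tab$fd, tolerance = 1e-5)
  }
  # hospital-side signs: rewards and fines shrink the illegal-operation basin
  tab <- sensitivity_signs(scn[[1]])
  gets <- function(q, par) tab$sign[tab$quantity == q & tab$parameter == par]
  expect_equal(gets("A1B1", "Ah"), "-")
  expect_equal(gets("A1B1", "Ph"), "-")
  expect_equal(gets("A1B1", "Ch1"), "+")
  expect_equal(gets("Vh1", "Ph"), "+")
  expect_equal(gets("Vh1", "Ah"), "+")
  expect_equal(gets("Vt1", "Pt"), "+")
  expect_equal(tab$derivative[tab$quantity == "A1B1" & tab$parameter == "Ah"],
               -0.25)
})

test_that("region measures respond monotonically to the mechanism levers", {
  # pointwise-monotone factor shifts make the grid measure exactly monotone
  for (s in 1:40) {
    p <- sample_valid_params(2000 + s)
    meas <- function(pp) threshold_geometry(game_params_vec(pp, strict = TRUE),
                                            "integral", n = 128)$measures
    m0 <- meas(unclass(p))
    bump <- function(nm, d) { q <- unclass(p); q[nm] <- q[nm] + d; q }
    expect_lte(meas(bump("Ph", 0.3))[["Vh2"]], m0[["Vh2"]])
    expect_lte(meas(bump("Ah", -min(0.3, p[["Ah"]] / 2)))[["Vh1"]], m0[["Vh1"]])
    expect_lte(meas(bump("Pt", 0.3))[["Vt2"]], m0[["Vt2"]])
    expect_lte(meas(bump("Ag", -min(0.3, p[["Ag"]] / 2)))[["Vg1"]], m0[["Vg1"]])
    expect_gte(meas(bump("Pg", 0.3))[["Vg1"]], m0[["Vg1"]])
    expect_lte(meas(bump("Cg", 0.3))[["Vg1"]], m0[["Vg1"]])
    expect_gte(meas(bump("Ah", -min(0.3, p[["Ah"]] / 2)))[["Vg1"]], m0[["Vg1"]])
  }
})

test_that("factor functions are monotone in the opponents' frequencies", {
  for (s in 1:40) {
    p <- sample_valid_params(2100 + s)
    a <- stats::runif(2, 0, 0.5); b <- a + stats::runif(2, 0, 0.5)
    expect_gte(G_factor(p, b[1], a[2]), G_factor(p, a[1], a[2]))
    expect_gte(G_factor(p, a[1], b[2]), G_factor(p, a[1], a[2]))
    for (mode in c("reference", "matrix"))
      expect_gte(J_factor(p, b[1], a[2], mode), J_factor(p, a[1], a[2], mode))
    # z-monotonicity of J holds in matrix mode (slope Pt); in reference mode
    # the extra x z (It1 - It2) term can overturn it, so it is not asserted
    expect_gte(J_factor(p, a[1], b[2], "matrix"),
               J_factor(p, a[1], a[2], "matrix"))
    expect_gte(H_factor(p, b[1], a[2]), H_factor(p, a[1], a[2]))
    expect_gte(H_factor(p, a[1], b[2]), H_factor(p, a[1], a[2]))
  }
})
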