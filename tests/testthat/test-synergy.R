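test_that("combination design halves the dilution and fixes partner IC30s", {
  berb <- alkaloid_ladder("berberine")
  copt <- alkaloid_ladder("coptisine")
  palm <- alkaloid_ladder("palmatine")

  des <- build_design(berb, list(copt, palm), start_dose = 10, n_steps = 8)
  expect_equal(des$dilution, 10 / 2^(0:7))
  expect_equal(des$fixed_partners$dose, c(0.95, 3.4))
  expect_equal(des$fixed_partners$agent, c("coptisine", "palmatine"))

  no30 <- copt[copt$level != 30, ]
  class(no30) <- class(copt)
  expect_error(build_design(berb, list(no30), 10), "IC30")
})

test_that("compute_ci implements the fixed-dose FE summation", {
  r <- compute_ci(0.59, 2.02, 0.95, level = 60)
  expect_equal(r$ci, 0.59 / 2.02 + 0.59 / 0.95)
  expect_equal(round(r$ci, 2), 0.91)

  sham <- compute_ci(3, 3)
  expect_identical(sham$ci, 1)

  triple <- compute_ci(3.47, 8.09, c(0.95, 3.4))
  expect_equal(signif(triple$ci, 2), 5.1)
  expect_length(triple$fe_fixed, 2)
  expect_equal(triple$ci, triple$fe_varied + sum(triple$fe_fixed))

  expect_error(compute_ci(0, 1), "positive")
  expect_error(compute_ci(1, 1, -0.5), "positive")
})

test_that("classical Loewe FIC is the iso-effective dose-fraction sum", {
  expect_equal(compute_classical_fic(c(0.5, 0.5), c(1, 1)), 1)
  # documented contrast with the fixed-dose CI at the same reference cell:
  # 0.4/1.48 + 0.95/1.27 = 0.270 + 0.748, not the fixed-dose 0.7
  expect_equal(compute_classical_fic(c(0.4, 0.95), c(1.48, 1.27)),
               1.0183, tolerance = 1e-4)
  expect_error(compute_classical_fic(numeric(0), numeric(0)), "non-empty")
  expect_error(compute_classical_fic(1, c(1, 2)), "equal length")
})

test_that("noise-free Loewe checkerboards give back the generator's tau", {
  berb <- berb_model()
  copt <- copt_model()
  for (tau in c(0.5, 1, 1.5)) {
    for (x in seq(10, 90, 20)) {
      # pick a checkerboard column whose partner dose stays below the
      # iso-effect contour, invert the simulated curve numerically for the
      # varied dose, then score the dose pair with the classical FIC
      fx <- 0.4 * tau * ic_at_level(copt, x)
      d <- combo_ic_oracle(berb, x, list(copt), fx, tau = tau)
      fic <- compute_classical_fic(c(d, fx),
                                   c(ic_at_level(berb, x),
                                     ic_at_level(copt, x)))
      expect_equal(fic, tau, tolerance = 0.01)
    }
  }
})

test_that("classification schemes are total with exact boundaries", {
  expect_setequal(fic_schemes(), c("schelz", "berenbaum", "table3_bold"))
  expect_error(classify(1, "chou"), "schelz")

  expect_identical(classify(0.43, "schelz"), "synergy")
  expect_identical(classify(0.91, "schelz"), "additive")
  expect_identical(classify(0.91, "table3_bold"), "synergy")

  # boundary semantics
  expect_identical(classify(0.5, "schelz"), "synergy")
  expect_identical(classify(1.0, "schelz"), "additive")
  expect_identical(classify(4.0, "schelz"), "antagonism")
  expect_identical(classify(1.0, "berenbaum"), "additive")
  expect_identical(classify(1 - 1e-12, "berenbaum"), "synergy")
  expect_identical(classify(1 + 1e-12, "berenbaum"), "antagonism")
  expect_identical(classify(1.0, "table3_bold"), "no synergy")

  # totality: every positive value receives exactly one label
  grid <- c(10^seq(-4, 4, length.out = 41), 0.5, 1, 4)
  for (s in fic_schemes()) {
    lab <- classify(grid, s)
    expect_true(all(!is.na(lab)))
    expect_length(lab, length(grid))
  }
  expect_error(classify(0, "schelz"), "positive")
})

test_that("fic_table scores and classifies every shared level", {
  combo <- alkaloid_ladder("berberine+coptisine")
  alone <- alkaloid_ladder("berberine")
  tab <- fic_table(combo, alone, c(coptisine = 0.95),
                   schemes = c("schelz", "table3_bold"))
  expect_equal(tab$level, seq(10, 90, 10))
  expect_equal(tab$ci, tab$fe_varied + tab$fe_coptisine)
  expect_identical(tab$table3_bold[tab$level == 60], "synergy")
  expect_identical(tab$schelz[tab$level == 60], "additive")
  # synergy weakens as the varied dose grows: CI increases with level here
  expect_true(all(diff(tab$ci) > 0))
})

test_that("isobologram points sit relative to the additivity line by FIC", {
  # sham: an agent split against itself lands on the line
  pt <- isobologram_points(0.6, 1.2, 0.6, 1.2)
  expect_equal(pt$fe_a + pt$fe_b, 1)

  # Loewe-synergistic generator puts every level strictly below the line
  berb <- berb_model()
  copt <- copt_model()
  lv <- seq(10, 90, 10)
  fx <- 0.3 * ic_at_level(copt, lv) # partner doses below each contour
  d <- vapply(seq_along(lv), function(i)
    combo_ic_oracle(berb, lv[i], list(copt), fx[i], tau = 0.5), numeric(1))
  pts <- do.call(rbind, lapply(seq_along(lv), function(i)
    isobologram_points(d[i], ic_at_level(berb, lv[i]), fx[i],
                       ic_at_level(copt, lv[i]))))
  expect_true(all(pts$fe_a + pts$fe_b < 1))
  expect_equal(pts$fic, rep(0.5, length(lv)), tolerance = 0.01)

  # no partner: degenerate single-axis output, flagged not failing
  deg <- isobologram_points(c(0.5, 1), 1)
  expect_true(attr(deg, "degenerate"))
  expect_identical(deg$fe_b, c(0, 0))
})
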