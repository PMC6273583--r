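test_that("Loewe identities hold for sham and single-agent combinations", {
  a <- fourpl(2, 1.5)
  # two identical agents at half the midpoint dose each: exactly additive
  expect_equal(as.numeric(
    simulate_combination_effect(a, a$ic50 / 2, list(a), a$ic50 / 2)),
    50, tolerance = 1e-7)
  # single agent, tau = 1 reduces to the plain curve
  expect_equal(as.numeric(simulate_combination_effect(a, a$ic50)),
               50, tolerance = 1e-7)
  for (d in c(0.3, 1, 5)) {
    expect_equal(as.numeric(simulate_combination_effect(a, d)),
                 simulate_effect(a, d), tolerance = 1e-6)
  }
})

test_that("synergy (tau < 1) shifts the combination curve left", {
  berb <- berb_model()
  copt <- copt_model()
  copt_ic30 <- ic_at_level(copt, 30)
  # at level 85 the IC30 partner load stays below tau = 0.5, so the
  # combination IC85 exists; synergy puts it far left of berberine alone
  ic85_syn <- combo_ic_oracle(berb, 85, list(copt), copt_ic30, tau = 0.5)
  ic85_add <- combo_ic_oracle(berb, 85, list(copt), copt_ic30, tau = 1)
  expect_lt(ic85_syn, ic85_add)
  expect_lt(ic85_add, ic_at_level(berb, 85))
  # antagonism shifts it right of the additive curve
  ic85_ant <- combo_ic_oracle(berb, 85, list(copt), copt_ic30, tau = 1.5)
  expect_gt(ic85_ant, ic85_add)
})

test_that("bisection solver agrees with the closed-form dose inverse", {
  withr::local_seed(43)
  for (i in 1:10) {
    varied <- fourpl(stats::runif(1, 0.5, 5), stats::runif(1, 0.7, 3))
    partner <- fourpl(stats::runif(1, 0.5, 5), stats::runif(1, 0.7, 3))
    tau <- stats::runif(1, 0.4, 2)
    level <- stats::runif(1, 15, 85)
    # keep the partner load below tau at every tested level so the varied
    # agent's iso-effect dose exists
    fdose <- 0.25 * tau * ic_at_level(partner, 10)
    d <- combination_ic(varied, level, list(partner), fdose, tau = tau)
    eff <- simulate_combination_effect(varied, d, list(partner), fdose,
                                       tau = tau)
    expect_equal(as.numeric(eff), level, tolerance = 1e-6)
  }
})

test_that("combination preconditions are enforced", {
  a <- fourpl(2, 1.5)
  shifted <- fourpl(2, 1.5, bottom = 5, top = 95)
  expect_error(simulate_combination_effect(a, 1, list(shifted), 1),
               "bottom = 0, top = 100")
  expect_error(simulate_combination_effect(a, -1, well = "C3"), "C3")
  expect_error(simulate_combination_effect(a, 1, tau = 0), "tau")
  expect_error(combination_ic(a, 50, list(a), 100), "fixed partners alone")
  below <- simulate_combination_effect(a, 1e-12)
  expect_equal(as.numeric(below), 0)
  expect_true(attr(below, "below_detection"))
})

test_that("kinetic plates honour exact signal arithmetic when noise is off", {
  lay <- dilution_layout("berberine", c(0.5, 2, 8), n_replicates = 1)
  agents <- list(berberine = berb_model())
  pl <- simulate_kinetic_plate(lay, agents, noise_model(0, 0), seed = 1)

  reads <- pl$reads
  inc_of <- function(w) {
    r <- reads[reads$well == w, ]
    post <- r[r$phase == "post", ]
    post$absorbance - (pl$meta$baseline + pl$meta$drift * post$time_min)
  }
  ctrl <- lay$well[lay$role == "negative_control"][1]
  expect_equal(inc_of(ctrl), pl$meta$control_increment, tolerance = 1e-12)

  # a dose-0 sample well would equal the control increment; fully inhibited
  # wells collapse onto the drift-extrapolated baseline
  lay2 <- plate_layout(rbind(lay,
    data.frame(well = "H12", sample_id = "berberine", role = "sample",
               dose = 0, replicate = 9)))
  pl2 <- simulate_kinetic_plate(lay2, agents, noise_model(0, 0), seed = 1)
  expect_equal(inc_of2 <- {
    r <- pl2$reads[pl2$reads$well == "H12" & pl2$reads$phase == "post", ]
    r$absorbance - (pl2$meta$baseline + pl2$meta$drift * r$time_min)
  }, pl2$meta$control_increment, tolerance = 1e-12)

  strong <- fourpl(1e-9, 4) # saturated at any tested dose: ~100% inhibition
  pl3 <- simulate_kinetic_plate(
    dilution_layout("x", 10, n_replicates = 1), list(x = strong),
    noise_model(0, 0), seed = 1)
  r3 <- pl3$reads[pl3$reads$phase == "post" &
                    pl3$reads$well %in%
                      pl3$layout$well[pl3$layout$role == "sample"], ]
  expect_equal(r3$absorbance,
               pl3$meta$baseline + pl3$meta$drift * r3$time_min,
               tolerance = 1e-9)
})

test_that("seeded plate generation is byte-identical", {
  lay <- dilution_layout(c("a", "b"), c(0.5, 2, 8), n_replicates = 3)
  agents <- list(a = berb_model(), b = copt_model())
  nm <- noise_model(0.003, 0.06, seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_kinetic_csv(simulate_kinetic_plate(lay, agents, nm), d1)
  write_kinetic_csv(simulate_kinetic_plate(lay, agents, nm), d2)
  expect_identical(readBin(file.path(d1, "plate.csv"), "raw", 1e6),
                   readBin(file.path(d2, "plate.csv"), "raw", 1e6))
  # different seed changes the bytes
  nm2 <- noise_model(0.003, 0.06, seed = 100)
  d3 <- withr::local_tempdir()
  write_kinetic_csv(simulate_kinetic_plate(lay, agents, nm2), d3)
  expect_false(identical(readBin(file.path(d1, "plate.csv"), "raw", 1e6),
                         readBin(file.path(d3, "plate.csv"), "raw", 1e6)))
})

test_that("plate generation validates its layout and agents", {
  lay <- dilution_layout("a", c(1, 2), n_replicates = 1)
  expect_error(simulate_kinetic_plate(lay, list(), noise_model(0, 0)),
               "no agent model for sample 'a'")
  no_ctrl <- lay[lay$role != "negative_control", ]
  expect_error(plate_layout(no_ctrl), "negative_control")
  dup <- rbind(lay, lay[1, ])
  expect_error(plate_layout(dup), "duplicate well")
  expect_error(noise_model(sd_abs = -1), "sd_abs")
})

test_that("reduce + fit on a noise-free plate recovers the generator", {
  agents <- list(berberine = berb_model(), coptisine = copt_model())
  lay <- dilution_layout(names(agents),
                         c(0.125, 0.25, 0.5, 1, 2, 4, 8), n_replicates = 1)
  pl <- simulate_kinetic_plate(lay, agents, noise_model(0, 0), seed = 5)
  red <- reduce_plate(pl)
  for (nm in names(agents)) {
    sub <- red[red$sample_id == nm & red$role == "sample", ]
    fit <- fit_4pl(inhibition ~ dose, sub)
    expect_equal(fit$ic50, agents[[nm]]$ic50,
                 tolerance = 0.001)            # ic50 within 0.1%
    expect_equal(fit$hill, agents[[nm]]$hill,
                 tolerance = 0.005)            # hill within 0.5%
  }
})

test_that("percent-scale generator is seeded and honest about its truth", {
  d1 <- simulate_dose_response(berb_model(), std_doses(), sd = 3,
                               n_replicates = 3, seed = 12)
  d2 <- simulate_dose_response(berb_model(), std_doses(), sd = 3,
                               n_replicates = 3, seed = 12)
  expect_identical(d1, d2)
  expect_true(all(d1$true_response >= 0 & d1$true_response <= 100))
  expect_false(all(d1$response == d1$true_response))
})
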