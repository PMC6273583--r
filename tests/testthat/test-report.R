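test_that("viability is the control-relative OD percentage", {
  expect_equal(viability_percent(0.8, 0.8), 100)
  expect_equal(viability_percent(0, 0.8), 0)
  expect_equal(viability_percent(0.4, 0.8), 50)
  expect_error(viability_percent(0.4, 0), "positive")
})

test_that("selectivity ratio divides toxicity by on-target potency", {
  expect_equal(selectivity_ratio(3.72, 0.031, display = TRUE), 120)
  expect_equal(selectivity_ratio(270.0, 87.77, display = TRUE), 3.1)
  expect_equal(selectivity_ratio(5, 5), 1)
  expect_error(selectivity_ratio(-1, 2), "positive")
  # unrounded value is retained by default
  expect_gt(selectivity_ratio(3.72, 0.031), 119)
})

test_that("replicate summaries use mean and n-1 standard deviation", {
  expect_equal(summarize_replicates(c(2, 2, 2)), list(mean = 2, sd = 0, n = 3))
  expect_equal(summarize_replicates(c(1, 2, 3))$sd, 1)
  expect_true(is.na(summarize_replicates(5)$sd))
  expect_error(summarize_replicates(numeric(0)), "no replicate")

  # seeded synthetic triplicate SDs track the generator sigma
  sigma <- 3
  sds <- vapply(1:200, function(s) {
    summarize_replicates(withr::with_seed(s, stats::rnorm(3, 50, sigma)))$sd
  }, numeric(1))
  # E[sd] for n=3 Gaussian = sigma * sqrt(2/pi) / c4 adjustments aside,
  # the mean of many triplicate SDs should sit near sigma
  expect_equal(mean(sds), sigma, tolerance = 0.15)
})

test_that("activity calls use the 80%-at-ceiling rule with active boundary", {
  expect_identical(activity_call(1250, 79.9), "inactive")
  expect_identical(activity_call(1250, 80.0), "active")
  expect_identical(activity_call(1250, 95.0), "active")
  expect_identical(activity_call(1250, c(10, 80, 99)),
                   c("inactive", "active", "active"))
})

example_fits <- function() {
  data.frame(
    sample = c("A", "A", "B", "C", "D", "E"),
    solvent = c("MeOH", "H2O", "MeOH", "MeOH", "MeOH", "MeOH"),
    ic50 = c(12, 90, 3, 400, 800, 1.5),
    sd = c(1, 8, 0.2, 30, 60, 0.1),
    inhibition_at_max = c(95, 88, 99, 60, 42, 97),
    stringsAsFactors = FALSE
  )
}

test_that("screen table renders NA for inactives and n/a for missing", {
  fits <- example_fits()
  tox <- data.frame(sample = c("A", "B"), solvent = "MeOH",
                    ic50 = c(120, 36), sd = c(10, 3))
  rep <- build_screen_table(fits, tox)
  expect_s3_class(rep, "screen_report")
  meoh <- rep$screen$ache_MeOH
  names(meoh) <- rep$screen$sample
  expect_identical(unname(meoh[c("C", "D")]), c("NA", "NA"))   # 2 inactive
  expect_match(meoh[["A"]], "±")
  # sample A has no CH2Cl2 extract in this screen: H2O column exists, and
  # samples without an H2O extract are n/a there
  expect_identical(rep$screen$ache_H2O[rep$screen$sample == "B"], "n/a")
  # actives carry 2-significant-figure selectivity ratios
  act <- rep$actives
  expect_equal(act$ratio_display[act$sample == "A" & act$solvent == "MeOH"],
               signif(120 / 12, 2))
  expect_equal(act$ratio[act$sample == "B"], 36 / 3)
})

test_that("screen table ordering, duplicates and empty input behave", {
  fits <- example_fits()
  fits$family <- c("F2", "F2", "F1", "F1", "F3", "F1")
  rep <- build_screen_table(fits)
  expect_identical(rep$screen$sample, c("B", "C", "E", "A", "D"))

  # an exact duplicate row is tolerated; a conflicting one errors
  expect_silent(build_screen_table(rbind(fits, fits[1, ])))
  conflict <- rbind(fits, transform(fits[1, ], ic50 = 999))
  expect_error(build_screen_table(conflict), "conflicting")

  empty <- build_screen_table(example_fits()[0, ])
  expect_equal(nrow(empty$screen), 0)
  expect_equal(nrow(empty$actives), 0)

  # determinism: identical input twice gives identical tables
  expect_identical(build_screen_table(fits), build_screen_table(fits))
})

test_that("recomputed ratios match the bundled screen reference", {
  ref <- screen_reference()
  ext <- ref[!is.na(ref$ic50_cos7), ]
  recomputed <- selectivity_ratio(ext$ic50_cos7, ext$ic50_ache,
                                  display = TRUE)
  agree <- recomputed == ext$ratio_printed
  # 8 of 9 extract rows agree at 2 significant figures; the ninth is a
  # reference-rounding case (10.65 printed as 10)
  expect_equal(sum(agree), 8)
  expect_identical(ext$sample[!agree], "Phellodendron chinense")
  expect_identical(ext$solvent[!agree], "MeOH")
})
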