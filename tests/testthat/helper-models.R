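# reference-like agents used across tests (slopes solved from the bundled
# single-agent IC10/IC90 pairs, rounded)
berb_model <- function() fourpl(1.48, 1.292, name = "berberine")
copt_model <- function() fourpl(1.27, 2.936, name = "coptisine")
palm_model <- function() fourpl(5.21, 1.992, name = "palmatine")

std_doses <- function() c(0.125, 0.25, 0.5, 1, 2, 4, 8, 16)

# independent numeric inversion oracle: solve predict(m, d) == level by
# root bracketing, no closed form
ic_oracle <- function(m, level) {
  stats::uniroot(function(d) predict(m, dose = d) - level,
                 lower = 1e-12, upper = 1e9, tol = 1e-12)$root
}

# numeric inversion of a simulated Loewe combination curve in the varied
# dose (independent of the closed-form combination_ic)
combo_ic_oracle <- function(varied, level, fixed, fixed_doses, tau = 1) {
  stats::uniroot(function(d)
    as.numeric(simulate_combination_effect(varied, d, fixed, fixed_doses,
                                           tau = tau)) - level,
    lower = 1e-12, upper = 1e9, tol = 1e-12)$root
}

# tolerance of one unit in the last printed digit; pass the printed value
# as a character string to preserve its precision
ulp_of <- function(printed) {
  dec <- vapply(strsplit(as.character(printed), ".", fixed = TRUE),
                function(p) if (length(p) > 1L) nchar(p[2]) else 0L,
                integer(1))
  10^(-dec)
}

# the bundled reference ladder CSV with printed values kept as strings
alkaloid_reference_chr <- function() {
  utils::read.csv(system.file("extdata", "alkaloid_ic_ladders.csv",
                              package = "ellmanfic", mustWork = TRUE),
                  colClasses = "character")
}
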