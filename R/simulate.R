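#' Percent effect of a single agent at a dose
#'
#' Evaluates an agent's 4PL inhibition curve. Thin, precondition-checked
#' wrapper around [predict.fourpl()] used by the synthetic plate generator;
#' errors name the offending well when one is given.
#'
#' @param agent a [fourpl()] model.
#' @param dose dose(s) in µg/mL, each >= 0.
#' @param well optional well id used in error messages.
#' @return Percent effect(s), monotone nondecreasing in dose, inside
#'   `[bottom, top]`.
#' @examples
#' simulate_effect(fourpl(1.48, 1.292), 1.48)  # 50
#' @export
simulate_effect <- function(agent, dose, well = NULL) {
  stopifnot(inherits(agent, "fourpl"))
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("negative or non-finite dose",
         if (!is.null(well)) paste0(" for well ", well),
         ": ", paste(dose[!is.finite(dose) | dose < 0], collapse = ", "))
  predict(agent, dose = dose)
}

#' Effect of a fixed-partner combination under Loewe additivity
#'
#' Solves for the percent effect `E` of a dose `d` of the varied agent plus
#' fixed partner doses `f_j`, under the interaction-indexed Loewe model
#' \deqn{\sum_i \frac{d_i}{D_i(E)} = \tau}
#' where `D_i(E)` is agent i's single-agent dose producing effect `E`
#' (closed-form 4PL inversion) and `tau` is the Loewe interaction index:
#' `tau = 1` is exact additivity, `tau < 1` synergy (the dose pool acts as
#' if larger), `tau > 1` antagonism. Each `d_i/D_i(E)` is strictly
#' decreasing in `E`, so the root is unique; it is found by bisection on
#' `E` to absolute tolerance `tol`.
#'
#' All agents must share `bottom = 0`, `top = 100` (the screening form).
#' With a single agent and `tau = 1` the solution reduces exactly to
#' [simulate_effect()]. A combination too dilute to register above the
#' numerical floor returns 0 with attribute `below_detection = TRUE`.
#'
#' @param varied the varied agent's [fourpl()] model.
#' @param dose dose of the varied agent (µg/mL, >= 0, scalar).
#' @param fixed list of partner [fourpl()] models (possibly empty).
#' @param fixed_doses numeric vector of partner doses, same length as
#'   `fixed`, each >= 0.
#' @param tau Loewe interaction index, > 0.
#' @param tol absolute bisection tolerance on the effect scale.
#' @param well optional well id for error messages.
#' @return Percent effect in `[0, 100)`.
#' @examples
#' a <- fourpl(2, 1.5)
#' simulate_combination_effect(a, dose = 1, fixed = list(a), fixed_doses = 1)
#' @export
simulate_combination_effect <- function(varied, dose, fixed = list(),
                                        fixed_doses = numeric(), tau = 1,
                                        tol = 1e-9, well = NULL) {
  agents <- c(list(varied), fixed)
  doses <- c(dose, fixed_doses)
  if (length(fixed) != length(fixed_doses))
    stop("'fixed' and 'fixed_doses' must have the same length")
  stopifnot(length(dose) == 1L)
  for (a in agents) {
    stopifnot(inherits(a, "fourpl"))
    if (a$bottom != 0 || a$top != 100)
      stop("combination simulation requires all agents with bottom = 0, top = 100")
  }
  if (any(!is.finite(doses)) || any(doses < 0))
    stop("negative or non-finite dose in combination",
         if (!is.null(well)) paste0(" for well ", well))
  if (!is.finite(tau) || tau <= 0)
    stop("'tau' must be a positive interaction index")
  if (all(doses == 0)) return(0)

  f <- function(E) {
    s <- 0
    for (i in seq_along(agents))
      if (doses[i] > 0) s <- s + doses[i] / ic_at_level(agents[[i]], E)
    s - tau
  }
  lo <- 1e-7
  hi <- 100 - 1e-7
  if (f(lo) < 0) { # even the floor effect over-predicts: below detection
    return(structure(0, below_detection = TRUE))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Varied-agent dose reaching a target effect in a Loewe combination
#'
#' Closed-form inverse of [simulate_combination_effect()] in the dose
#' direction: at effect level `x` the varied dose is
#' `D_v(x) * (tau - sum_j f_j / D_j(x))`. Errors if the fixed partners alone
#' already reach the level.
#'
#' @inheritParams simulate_combination_effect
#' @param level target percent effect in (0, 100).
#' @return Dose of the varied agent in µg/mL.
#' @export
combination_ic <- function(varied, level, fixed = list(),
                           fixed_doses = numeric(), tau = 1) {
  stopifnot(inherits(varied, "fourpl"), length(level) == 1L,
            length(fixed) == length(fixed_doses))
  partner_load <- 0
  for (j in seq_along(fixed))
    partner_load <- partner_load + fixed_doses[j] / ic_at_level(fixed[[j]], level)
  d <- ic_at_level(varied, level) * (tau - partner_load)
  if (d <= 0)
    stop("fixed partners alone reach effect level ", level,
         " (no positive varied dose exists)")
  d
}

#' Replicate noise model for synthetic plates
#'
#' Noise is applied to the simulated absorbance reads, mimicking the
#' instrument: `sd_abs` is additive Gaussian noise (absorbance units) on
#' every read, `sd_rel` multiplies the enzymatic rate (fractional,
#' well-to-well pipetting/enzyme variability). Identical seeds give
#' bit-identical plates.
#'
#' @param sd_abs additive read noise, absorbance units, >= 0.
#' @param sd_rel multiplicative rate noise as a fraction, >= 0.
#' @param n_replicates replicate wells per (sample, dose), >= 1.
#' @param seed optional integer seed.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(sd_abs = 0.003, sd_rel = 0.06, n_replicates = 3,
                        seed = NULL) {
  stopifnot(sd_abs >= 0, sd_rel >= 0, n_replicates >= 1)
  structure(list(sd_abs = sd_abs, sd_rel = sd_rel,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "noise_model")
}

#' Plate layout
#'
#' Validates a well-map data frame: columns `well`, `sample_id`, `role`
#' (one of sample, negative_control, positive_control, blank), `dose`
#' (µg/mL) and `replicate`. Well ids must be unique, at least one negative
#' control (solvent only) must be present — percent inhibition is undefined
#' without one — and sample wells need a non-negative dose.
#'
#' @param wells a data frame as described.
#' @return The validated data frame with class `"plate_layout"`.
#' @export
plate_layout <- function(wells) {
  req <- c("well", "sample_id", "role", "dose", "replicate")
  miss <- setdiff(req, names(wells))
  if (length(miss))
    stop("layout is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(wells$well))
    stop("duplicate well id(s): ",
         paste(unique(wells$well[duplicated(wells$well)]), collapse = ", "))
  roles <- c("sample", "negative_control", "positive_control", "blank")
  if (!all(wells$role %in% roles))
    stop("unknown role(s): ",
         paste(setdiff(unique(wells$role), roles), collapse = ", "))
  if (!any(wells$role == "negative_control"))
    stop("layout has no negative_control well; percent inhibition is undefined")
  smp <- wells$role == "sample"
  if (any(smp & (is.na(wells$dose) | wells$dose < 0)))
    stop("sample wells require a non-negative dose")
  wells <- as.data.frame(wells)
  class(wells) <- c("plate_layout", "data.frame")
  wells
}

#' Serial-dilution plate layout for one or more samples
#'
#' Convenience builder: one column block per sample with an n-point dose
#' series, replicate rows, plus solvent-only negative-control wells. Wells
#' are labelled row-letter + column-number as on a 96-well plate.
#'
#' @param samples character vector of sample ids.
#' @param doses numeric dose vector applied to each sample.
#' @param n_replicates replicate wells per dose.
#' @param n_controls number of negative-control wells.
#' @return A [plate_layout()].
#' @export
dilution_layout <- function(samples, doses, n_replicates = 3,
                            n_controls = 3) {
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      dose = doses, sample_id = samples,
                      stringsAsFactors = FALSE)
  n <- nrow(grid) + n_controls
  if (n > 96) stop("layout needs ", n, " wells; a plate has 96")
  ids <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))[seq_len(n)]
  ctrl <- data.frame(replicate = seq_len(n_controls), dose = 0,
                     sample_id = "DMSO", stringsAsFactors = FALSE)
  wells <- rbind(
    data.frame(well = ids[seq_len(nrow(grid))], grid,
               role = "sample", stringsAsFactors = FALSE),
    data.frame(well = ids[nrow(grid) + seq_len(n_controls)], ctrl,
               role = "negative_control", stringsAsFactors = FALSE)
  )
  plate_layout(wells[c("well", "sample_id", "role", "dose", "replicate")])
}

#' Simulate a kinetic Ellman plate
#'
#' Generates the raw artifact the reduction stage consumes: for every well,
#' pre-enzyme absorbance reads at 0, 3, 6 and 9 min following a linear
#' spontaneous drift, then a single post-enzyme read whose increment over
#' the drift-extrapolated baseline is proportional to
#' `(100 - inhibition) / 100` of the control increment. Read noise follows
#' the well's [noise_model()]; the noiseless inhibition of every well is
#' recorded in the ground-truth table. Negative-control wells have 0%
#' inhibition by construction; positive controls use `positive_inhibition`;
#' blanks receive no enzymatic increment.
#'
#' @param layout a [plate_layout()].
#' @param agents named list of [fourpl()] models, keyed by `sample_id`.
#' @param noise a [noise_model()].
#' @param drift spontaneous (non-enzymatic) drift, absorbance/min.
#' @param control_increment post-enzyme absorbance increment of an
#'   uninhibited well over 3 min incubation.
#' @param baseline absorbance at t = 0 before drift.
#' @param pre_times pre-enzyme read times in minutes.
#' @param post_time post-enzyme read time in minutes (> max pre time).
#' @param positive_inhibition percent inhibition assigned to positive
#'   control wells.
#' @param seed integer seed; defaults to the noise model's. Identical seeds
#'   give bit-identical plates.
#' @return An object of class `"kinetic_plate"`: list with `layout`,
#'   `reads` (long data frame: well, time_min, phase, absorbance), `truth`
#'   (well, sample_id, dose, true_inhibition) and `meta` (all generator
#'   parameters, the seed, and the clipping rule: absorbances below 0 are
#'   set to 0).
#' @export
simulate_kinetic_plate <- function(layout, agents, noise = noise_model(),
                                   drift = 0.0015, control_increment = 0.25,
                                   baseline = 0.08,
                                   pre_times = c(0, 3, 6, 9), post_time = 12,
                                   positive_inhibition = 98,
                                   seed = noise$seed) {
  layout <- plate_layout(layout)
  stopifnot(inherits(noise, "noise_model"), post_time > max(pre_times),
            control_increment > 0)
  inh <- numeric(nrow(layout))
  for (i in seq_len(nrow(layout))) {
    inh[i] <- switch(layout$role[i],
      negative_control = 0,
      positive_control = positive_inhibition,
      blank = NA_real_,
      sample = {
        sid <- layout$sample_id[i]
        if (is.null(agents[[sid]]))
          stop("no agent model for sample '", sid, "' (well ",
               layout$well[i], ")")
        simulate_effect(agents[[sid]], layout$dose[i], well = layout$well[i])
      })
  }

  gen <- function() {
    reads <- vector("list", nrow(layout))
    for (i in seq_len(nrow(layout))) {
      pre <- baseline + drift * pre_times +
        stats::rnorm(length(pre_times), 0, noise$sd_abs)
      base_post <- baseline + drift * post_time
      inc <- if (layout$role[i] == "blank") 0 else
        control_increment * (100 - inh[i]) / 100 *
          (1 + stats::rnorm(1, 0, noise$sd_rel))
      post <- base_post + inc + stats::rnorm(1, 0, noise$sd_abs)
      reads[[i]] <- data.frame(
        well = layout$well[i],
        time_min = c(pre_times, post_time),
        phase = c(rep("pre", length(pre_times)), "post"),
        absorbance = pmax(c(pre, post), 0), # clip rule: negatives -> 0
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, reads)
  }
  reads <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())

  structure(list(
    layout = layout,
    reads = reads,
    truth = data.frame(well = layout$well, sample_id = layout$sample_id,
                       dose = layout$dose, true_inhibition = inh,
                       stringsAsFactors = FALSE),
    meta = list(seed = seed, drift = drift,
                control_increment = control_increment, baseline = baseline,
                pre_times = pre_times, post_time = post_time,
                sd_abs = noise$sd_abs, sd_rel = noise$sd_rel,
                clip = "absorbance values below 0 are set to 0")
  ), class = "kinetic_plate")
}

#' @export
print.kinetic_plate <- function(x, ...) {
  cat("Synthetic kinetic plate:", nrow(x$layout), "wells,",
      nrow(x$reads), "reads\n")
  cat("seed:", if (is.null(x$meta$seed)) "none" else x$meta$seed,
      " drift:", x$meta$drift, "AU/min\n")
  invisible(x)
}

#' Simulate a percent-scale dose-response series
#'
#' Shortcut generator for fitting studies: true 4PL (or Loewe combination)
#' effects at the given doses plus additive Gaussian noise directly on the
#' percent scale. The instrument-level path is
#' [simulate_kinetic_plate()] + [reduce_plate()]; this generator is for
#' estimator calibration where read-out noise in percent units is the
#' stated condition.
#'
#' @param agent a [fourpl()] model (the varied agent).
#' @param doses dose vector, µg/mL.
#' @param sd Gaussian noise SD on the percent scale.
#' @param n_replicates replicates per dose.
#' @param fixed,fixed_doses,tau optional Loewe fixed partners, as in
#'   [simulate_combination_effect()].
#' @param seed optional integer seed.
#' @return Data frame with columns `dose`, `replicate`, `response`,
#'   `true_response`.
#' @export
simulate_dose_response <- function(agent, doses, sd = 0, n_replicates = 1,
                                   fixed = list(), fixed_doses = numeric(),
                                   tau = 1, seed = NULL) {
  truth <- if (length(fixed)) {
    vapply(doses, function(d)
      as.numeric(simulate_combination_effect(agent, d, fixed, fixed_doses,
                                             tau = tau)), numeric(1))
  } else {
    simulate_effect(agent, doses)
  }
  out <- data.frame(
    dose = rep(doses, each = n_replicates),
    replicate = rep(seq_len(n_replicates), times = length(doses)),
    true_response = rep(truth, each = n_replicates)
  )
  gen <- function() out$true_response + stats::rnorm(nrow(out), 0, sd)
  out$response <- if (sd == 0) out$true_response
                  else if (is.null(seed)) gen()
                  else withr::with_seed(seed, gen())
  out
}
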