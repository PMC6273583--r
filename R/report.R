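#' Screening activity call at the assay ceiling
#'
#' A sample is called inactive when it inhibits less than `threshold`
#' percent of enzyme activity at the top screening concentration
#' (default ceiling 1250 µg/mL); exactly `threshold` at the ceiling is
#' called active (documented boundary decision).
#'
#' @param max_tested_dose top concentration tested, µg/mL.
#' @param inhibition_at_max percent inhibition observed there.
#' @param ceiling configured screen ceiling, µg/mL.
#' @param threshold percent-inhibition activity cutoff.
#' @return `"active"` or `"inactive"` (vectorized).
#' @examples
#' activity_call(1250, c(79.9, 80, 95))
#' @export
activity_call <- function(max_tested_dose, inhibition_at_max,
                          ceiling = 1250, threshold = 80) {
  ifelse(inhibition_at_max < threshold, "inactive", "active")
}

#' Percent viability relative to the untreated control
#'
#' MTT read-out: `100 * od_sample / od_control`, the percentage of viable
#' cells compared to control wells.
#'
#' @param od_sample optical density of treated well(s).
#' @param od_control optical density of the control; must be positive.
#' @return Percent viability.
#' @examples
#' viability_percent(0.4, 0.8)  # 50
#' @export
viability_percent <- function(od_sample, od_control) {
  stopifnot(length(od_control) == 1L, is.finite(od_control))
  if (od_control <= 0) stop("control OD must be positive")
  100 * od_sample / od_control
}

#' Cytotoxicity selectivity ratio
#'
#' Ratio of the cytotoxic IC50 (viability curve midpoint in the cell line)
#' to the on-target inhibitory IC50. A high ratio denotes a wide window
#' between activity and toxicity. Display convention is 2 significant
#' figures (round half to even); the unrounded value is what downstream
#' computation should use.
#'
#' @param ic50_toxicity cytotoxic IC50, µg/mL, > 0 (vectorized).
#' @param ic50_inhibition on-target IC50, µg/mL, > 0.
#' @param display if `TRUE`, return the 2-significant-figure display value.
#' @return The ratio (dimensionless).
#' @examples
#' selectivity_ratio(3.72, 0.031, display = TRUE)  # 120
#' @export
selectivity_ratio <- function(ic50_toxicity, ic50_inhibition,
                              display = FALSE) {
  v <- c(ic50_toxicity, ic50_inhibition)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("both IC50 values must be positive and finite")
  r <- ic50_toxicity / ic50_inhibition
  if (display) signif(r, 2) else r
}

#' Replicate summary: mean and sample standard deviation
#'
#' The screening summary convention, mean ± SD with the n - 1 denominator.
#'
#' @param values numeric replicate values (percent or µg/mL); at least one,
#'   at least two for a finite SD.
#' @return List with `mean`, `sd` (`NA` when n = 1) and `n`.
#' @examples
#' summarize_replicates(c(1, 2, 3))  # mean 2, sd 1
#' @export
summarize_replicates <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no replicate values to summarize")
  list(mean = mean(values),
       sd = if (length(values) >= 2L) stats::sd(values) else NA_real_,
       n = length(values))
}

# "x ± y" cell used in the wide screen tables
fmt_pm <- function(m, s, digits = 4) {
  ifelse(is.na(m), NA_character_,
         ifelse(is.na(s), as.character(signif(m, digits)),
                paste0(signif(m, digits), " ± ", signif(s, digits))))
}

#' Assemble the screen summary tables
#'
#' Aggregates per-sample fits, activity calls and cytotoxicity into the
#' two standard screening artifacts: a wide screen table (one row per
#' sample, one inhibition-IC50 and one cytotoxicity-IC50 column per
#' solvent, inactive samples rendered `NA`, missing extracts `n/a`) and an
#' actives table restricted to active samples with their selectivity
#' ratios (2 significant figures).
#'
#' @param fits data frame of inhibition results: `sample`, `solvent`,
#'   `ic50`, `sd`, `inhibition_at_max`; optionally `family` for ordering.
#' @param tox optional data frame of cytotoxicity results: `sample`,
#'   `solvent`, `ic50`, `sd`.
#' @param ceiling,threshold activity-call configuration
#'   (see [activity_call()]).
#' @return List of class `"screen_report"` with `screen` (wide table),
#'   `actives` (long table with `ratio` and `ratio_display`) and `calls`
#'   (per sample x solvent activity calls).
#' @export
build_screen_table <- function(fits, tox = NULL, ceiling = 1250,
                               threshold = 80) {
  req <- c("sample", "solvent", "ic50", "sd", "inhibition_at_max")
  miss <- setdiff(req, names(fits))
  if (length(miss))
    stop("fits table is missing column(s): ", paste(miss, collapse = ", "))
  key <- paste(fits$sample, fits$solvent)
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    conflict <- vapply(dups, function(k) {
      g <- fits[key == k, req[3:5]]
      nrow(unique(g)) > 1L
    }, logical(1))
    if (any(conflict))
      stop("conflicting duplicate rows for: ",
           paste(dups[conflict], collapse = ", "))
    fits <- fits[!duplicated(key), , drop = FALSE]
    key <- key[!duplicated(key)]
  }

  calls <- data.frame(
    sample = fits$sample, solvent = fits$solvent,
    call = activity_call(ceiling, fits$inhibition_at_max,
                         ceiling = ceiling, threshold = threshold),
    stringsAsFactors = FALSE
  )

  solvents <- sort(unique(fits$solvent))
  samples <- unique(fits[, intersect(c("family", "sample"), names(fits)),
                         drop = FALSE])
  ord <- if ("family" %in% names(samples))
    order(samples$family, samples$sample) else order(samples$sample)
  samples <- samples[ord, , drop = FALSE]

  cell <- function(smp, sol) {
    i <- which(fits$sample == smp & fits$solvent == sol)
    if (!length(i)) return("n/a") # extract not prepared / not analysed
    if (calls$call[i] == "inactive") return("NA")
    fmt_pm(fits$ic50[i], fits$sd[i])
  }
  tox_cell <- function(smp, sol) {
    if (is.null(tox)) return(NULL)
    i <- which(tox$sample == smp & tox$solvent == sol)
    if (!length(i)) "n/a" else fmt_pm(tox$ic50[i], tox$sd[i])
  }

  screen <- data.frame(sample = samples$sample, stringsAsFactors = FALSE)
  if ("family" %in% names(samples)) screen$family <- samples$family
  for (sol in solvents)
    screen[[paste0("ache_", sol)]] <-
      vapply(samples$sample, cell, character(1), sol = sol)
  if (!is.null(tox))
    for (sol in sort(unique(tox$solvent)))
      screen[[paste0("cos7_", sol)]] <-
        vapply(samples$sample, tox_cell, character(1), sol = sol)
  rownames(screen) <- NULL

  act <- fits[calls$call == "active", , drop = FALSE]
  actives <- act[c("sample", "solvent", "ic50", "sd")]
  names(actives)[3:4] <- c("ic50_ache", "sd_ache")
  if (!is.null(tox)) {
    m <- match(paste(act$sample, act$solvent), paste(tox$sample, tox$solvent))
    actives$ic50_cos7 <- tox$ic50[m]
    actives$sd_cos7 <- tox$sd[m]
    ok <- !is.na(actives$ic50_cos7)
    actives$ratio <- NA_real_
    actives$ratio[ok] <- selectivity_ratio(actives$ic50_cos7[ok],
                                           actives$ic50_ache[ok])
    actives$ratio_display <- signif(actives$ratio, 2)
  }
  rownames(actives) <- NULL

  structure(list(screen = screen, actives = actives, calls = calls),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Screen report:", nrow(x$screen), "samples,",
      sum(x$calls$call == "active"), "active calls\n")
  print(utils::head(x$screen, 10))
  invisible(x)
}

#' Bundled reference IC ladders for alkaloid combinations
#'
#' Published reference measurements (Ellman AChE assay) for the
#' isoquinoline alkaloids berberine, coptisine and palmatine: single-agent
#' IC10..IC90 ladders and every fixed-partner combination ladder
#' (partner(s) held at their IC30), together with the published per-level
#' combination-index values for the combination rows. Concentrations in
#' µg/mL. These printed values serve as golden inputs for the CI
#' convention and the ladder-consistency checks; the
#' `palmatine + coptisine` series' published CI row is internally
#' inconsistent with every summation convention and is excluded from
#' golden comparisons (see the methods vignette).
#'
#' @return Data frame with columns `series`, `varied`, `partners`
#'   (semicolon-separated, empty for single agents), `level`, `ic`
#'   (µg/mL) and `ci_printed` (`NA` on single-agent rows).
#' @export
alkaloid_reference <- function() {
  path <- system.file("extdata", "alkaloid_ic_ladders.csv",
                      package = "ellmanfic", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' One series of the bundled alkaloid reference as an IC ladder
#'
#' @param series series name as in [alkaloid_reference()] (e.g.
#'   `"berberine"`, `"berberine+coptisine"`).
#' @return An `ic_ladder` data frame (`agent` = series name).
#' @export
alkaloid_ladder <- function(series) {
  ref <- alkaloid_reference()
  rows <- ref[ref$series == series, , drop = FALSE]
  if (!nrow(rows))
    stop("unknown series '", series, "'; available: ",
         paste(unique(ref$series), collapse = ", "))
  out <- data.frame(agent = series, level = rows$level, ic = rows$ic,
                    stringsAsFactors = FALSE)
  out <- out[order(out$level), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ic_ladder", "data.frame")
  out
}

#' Bundled reference screen results (most active extracts)
#'
#' Published IC50 summary (mean ± SD, µg/mL) for the most active TCM plant
#' extracts and the pure reference compounds: AChE inhibition IC50,
#' COS7 cytotoxicity IC50 and the published selectivity ratio. Used as the
#' golden input for the selectivity-ratio and headline-potency checks.
#'
#' @return Data frame with columns `sample`, `solvent`, `ic50_ache`,
#'   `sd_ache`, `ic50_cos7`, `sd_cos7`, `ratio_printed`.
#' @export
screen_reference <- function() {
  path <- system.file("extdata", "screen_ic50.csv",
                      package = "ellmanfic", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reference 4PL models for the three alkaloids
#'
#' Reconstructs 0-100 logistic models for berberine, coptisine and
#' palmatine from the bundled single-agent ladders
#' ([fourpl_from_ladder()] on the IC10/IC90 pair). These parameterize the
#' synthetic generator's default agents.
#'
#' @return Named list of [fourpl()] models.
#' @export
reference_alkaloid_models <- function() {
  out <- lapply(c("berberine", "coptisine", "palmatine"), function(a)
    fourpl_from_ladder(alkaloid_ladder(a), name = a))
  names(out) <- c("berberine", "coptisine", "palmatine")
  out
}
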