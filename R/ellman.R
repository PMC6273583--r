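#' Spontaneous drift of a pre-enzyme kinetic trace
#'
#' Least-squares slope of the pre-enzyme absorbance reads against time.
#' The substrate/chromogen mix hydrolyses slowly on its own; reads taken
#' before enzyme addition estimate that spontaneous signal so it can be
#' subtracted from the enzymatic increment. The linearity diagnostic is the
#' maximum absolute residual of the line; traces exceeding `threshold` are
#' flagged `drift_nonlinear`.
#'
#' @param times pre-enzyme read times (min), at least 2.
#' @param absorbances matching absorbance reads.
#' @param threshold max-|residual| above which the trace is flagged
#'   (absorbance units).
#' @return List with `slope` (absorbance/min), `intercept`, `max_resid`
#'   and logical `nonlinear`.
#' @examples
#' spontaneous_drift(c(0, 3, 6, 9), 0.1 + 0.002 * c(0, 3, 6, 9))
#' @export
spontaneous_drift <- function(times, absorbances, threshold = 0.01) {
  if (length(times) < 2L)
    stop("at least 2 pre-enzyme reads are required to estimate drift")
  stopifnot(length(times) == length(absorbances),
            all(is.finite(times)), all(is.finite(absorbances)))
  tb <- mean(times)
  ab <- mean(absorbances)
  slope <- sum((times - tb) * (absorbances - ab)) / sum((times - tb)^2)
  intercept <- ab - slope * tb
  resid <- absorbances - (intercept + slope * times)
  max_resid <- max(abs(resid))
  list(slope = slope, intercept = intercept, max_resid = max_resid,
       nonlinear = max_resid > threshold)
}

#' Drift-corrected enzymatic signal of one well
#'
#' The post-enzyme absorbance increment over the drift-extrapolated
#' baseline:
#' `post_abs - (last_pre_abs + slope * (post_time - last_pre_time))`.
#' Negative values are possible under noise and are flagged
#' (`negative_rate`) rather than clipped.
#'
#' @param last_pre_time,last_pre_abs time (min) and absorbance of the final
#'   pre-enzyme read.
#' @param post_time,post_abs time and absorbance of the post-enzyme read.
#' @param slope spontaneous drift, absorbance/min (from
#'   [spontaneous_drift()]).
#' @return List with `signal` (absorbance) and logical `negative_rate`.
#' @export
enzymatic_signal <- function(last_pre_time, last_pre_abs,
                             post_time, post_abs, slope) {
  stopifnot(is.finite(post_abs), is.finite(last_pre_abs), is.finite(slope),
            post_time > last_pre_time)
  signal <- post_abs - (last_pre_abs + slope * (post_time - last_pre_time))
  list(signal = signal, negative_rate = signal < 0)
}

#' Percent inhibition relative to the negative control
#'
#' `100 * (1 - sample_signal / control_signal)`. Values outside `[0, 100]`
#' are reported as-is — clamping is a presentation choice and would bias
#' the tails of a downstream 4PL fit. A non-positive control signal is a
#' plate-level failure: inhibition is then undefined.
#'
#' @param sample_signal enzymatic signal(s) of sample wells (absorbance).
#' @param control_signal mean enzymatic signal of negative-control wells;
#'   must be positive.
#' @return Percent inhibition, same length as `sample_signal`.
#' @examples
#' percent_inhibition(0.025, 0.100)  # 75
#' @export
percent_inhibition <- function(sample_signal, control_signal) {
  stopifnot(length(control_signal) == 1L, is.finite(control_signal))
  if (control_signal <= 0)
    stop("control signal must be positive (plate-level failure: ",
         "percent inhibition is undefined)")
  100 * (1 - sample_signal / control_signal)
}

#' Reduce a kinetic plate to per-well percent inhibition
#'
#' Runs the full Ellman reduction: per-well spontaneous drift, drift-
#' corrected post-enzyme signal, and percent inhibition relative to the
#' mean signal of all negative-control wells on the plate. QC flags
#' (`drift_nonlinear`, `negative_rate`, `na_read`) travel with each well;
#' flagged-unreadable wells get `NA` inhibition but do not stop the plate.
#'
#' @param x a `kinetic_plate` from [simulate_kinetic_plate()], a list with
#'   `layout` and `records` as from [read_kinetic_csv()], or a path to a
#'   kinetic CSV.
#' @param drift_threshold linearity flag threshold passed to
#'   [spontaneous_drift()].
#' @return A data frame of class `"inhibition_table"`: one row per
#'   non-blank well with `well`, `sample_id`, `role`, `dose`, `replicate`,
#'   `slope`, `signal`, `inhibition`, `flags` (semicolon-joined). The mean
#'   control signal is attached as attribute `control_signal`.
#' @export
reduce_plate <- function(x, drift_threshold = 0.01) {
  if (is.character(x)) x <- read_kinetic_csv(x)
  if (inherits(x, "kinetic_plate"))
    x <- list(layout = x$layout, records = x$reads, flagged = character(0))
  layout <- plate_layout(x$layout)
  rec <- x$records
  flagged <- if (is.null(x$flagged)) character(0) else x$flagged

  keep <- layout$role != "blank"
  wells <- layout$well[keep]
  n <- length(wells)
  slope <- signal <- numeric(n)
  flags <- character(n)
  for (i in seq_len(n)) {
    w <- wells[i]
    rows <- rec[rec$well == w, ]
    pre <- rows[rows$phase == "pre", ]
    post <- rows[rows$phase == "post", ]
    fl <- character(0)
    if (w %in% flagged || anyNA(pre$absorbance) || anyNA(post$absorbance)) {
      slope[i] <- NA_real_
      signal[i] <- NA_real_
      flags[i] <- "na_read"
      next
    }
    if (nrow(post) != 1L)
      stop("well ", w, ": expected exactly one post-enzyme read")
    dr <- spontaneous_drift(pre$time_min, pre$absorbance,
                            threshold = drift_threshold)
    last <- which.max(pre$time_min)
    sg <- enzymatic_signal(pre$time_min[last], pre$absorbance[last],
                           post$time_min, post$absorbance, dr$slope)
    slope[i] <- dr$slope
    signal[i] <- sg$signal
    if (dr$nonlinear) fl <- c(fl, "drift_nonlinear")
    if (sg$negative_rate) fl <- c(fl, "negative_rate")
    flags[i] <- paste(fl, collapse = ";")
  }

  is_ctrl <- layout$role[keep] == "negative_control"
  ctrl_signal <- signal[is_ctrl & !is.na(signal)]
  if (!length(ctrl_signal))
    stop("no usable negative-control well on the plate")
  control_signal <- mean(ctrl_signal)

  inhibition <- rep(NA_real_, n)
  ok <- !is.na(signal)
  inhibition[ok] <- percent_inhibition(signal[ok], control_signal)

  out <- data.frame(
    well = wells,
    sample_id = layout$sample_id[keep],
    role = layout$role[keep],
    dose = layout$dose[keep],
    replicate = layout$replicate[keep],
    slope = slope, signal = signal, inhibition = inhibition,
    flags = flags, stringsAsFactors = FALSE
  )
  attr(out, "control_signal") <- control_signal
  class(out) <- c("inhibition_table", "data.frame")
  out
}

#' Aggregate replicate inhibition values
#'
#' Mean and sample SD (n - 1) of percent inhibition per (sample, dose),
#' the summary convention for triplicate screening wells.
#'
#' @param tbl an `inhibition_table` from [reduce_plate()] (or any data
#'   frame with `sample_id`, `dose`, `inhibition`).
#' @return Data frame with `sample_id`, `dose`, `n`, `inhibition`
#'   (mean) and `sd`.
#' @export
aggregate_inhibition <- function(tbl) {
  stopifnot(all(c("sample_id", "dose", "inhibition") %in% names(tbl)))
  if (!is.null(tbl$role)) tbl <- tbl[tbl$role == "sample", , drop = FALSE]
  sp <- split(tbl, list(tbl$sample_id, tbl$dose), drop = TRUE)
  rows <- lapply(sp, function(g) {
    s <- summarize_replicates(g$inhibition[!is.na(g$inhibition)])
    data.frame(sample_id = g$sample_id[1], dose = g$dose[1],
               n = s$n, inhibition = s$mean, sd = s$sd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$dose), , drop = FALSE]
  rownames(out) <- NULL
  out
}
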