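#' Write a synthetic kinetic plate to CSV
#'
#' Writes the long-form kinetic dialect consumed by [read_kinetic_csv()]:
#' one row per (well, timepoint) with columns `well`, `sample_id`, `role`,
#' `dose`, `replicate`, `time_min`, `phase`, `absorbance`. A ground-truth
#' CSV (`well`, `sample_id`, `dose`, `true_inhibition`) and a YAML metadata
#' echo (generator parameters, seed, clipping rule) are written alongside.
#' Output is byte-deterministic: numbers are formatted with fixed precision
#' and row order follows the layout.
#'
#' @param plate a [simulate_kinetic_plate()] result.
#' @param dir output directory (created if needed).
#' @param stem file name stem; files are `<stem>.csv`,
#'   `<stem>_truth.csv`, `<stem>_meta.yaml`.
#' @return Invisibly, the kinetic CSV path.
#' @export
write_kinetic_csv <- function(plate, dir, stem = "plate") {
  stopifnot(inherits(plate, "kinetic_plate"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", dir)
  long <- merge(plate$reads, plate$layout, by = "well", sort = FALSE)
  long <- long[order(match(long$well, plate$layout$well), long$time_min),
               c("well", "sample_id", "role", "dose", "replicate",
                 "time_min", "phase", "absorbance")]
  path <- file.path(dir, paste0(stem, ".csv"))
  write_table_csv(long, path,
                  formats = c(dose = "%.6g", absorbance = "%.6f",
                              time_min = "%g"))
  write_table_csv(plate$truth, file.path(dir, paste0(stem, "_truth.csv")),
                  formats = c(dose = "%.6g", true_inhibition = "%.9f"))
  yaml::write_yaml(plate$meta, file.path(dir, paste0(stem, "_meta.yaml")))
  invisible(path)
}

#' Read a long-form kinetic plate CSV
#'
#' Parses the dialect written by [write_kinetic_csv()] back into a layout
#' and per-well kinetic records. Hard errors on a missing required column
#' or a duplicated (well, phase, time) read; a non-numeric absorbance makes
#' that well flagged (`na_read`) while the rest of the plate parses.
#' Pre-enzyme reads must be exactly at 0, 3, 6 and 9 min and each well must
#' carry a single post-enzyme read later than 9 min.
#'
#' @param path CSV file path.
#' @return A list with `layout` (a [plate_layout()]), `records` (long data
#'   frame of reads) and `flagged` (character vector of well ids with
#'   unreadable absorbances).
#' @export
read_kinetic_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("well", "sample_id", "role", "dose", "replicate",
           "time_min", "phase", "absorbance")
  miss <- setdiff(req, names(raw))
  if (length(miss))
    stop("kinetic CSV is missing column(s): ", paste(miss, collapse = ", "))
  num <- function(x) suppressWarnings(as.numeric(x))
  raw$dose <- num(raw$dose)
  raw$replicate <- as.integer(num(raw$replicate))
  raw$time_min <- num(raw$time_min)
  bad_time <- which(!is.finite(raw$time_min))
  if (length(bad_time))
    stop("unparseable time_min at data line(s) ",
         paste(bad_time, collapse = ", "))
  abs_num <- num(raw$absorbance)
  flagged <- sort(unique(raw$well[!is.finite(abs_num)]))
  raw$absorbance <- abs_num

  key <- paste(raw$well, raw$phase, raw$time_min)
  if (anyDuplicated(key)) {
    dup <- raw$well[duplicated(key)]
    stop("duplicate read for well(s): ", paste(unique(dup), collapse = ", "))
  }

  for (w in unique(raw$well)) {
    rows <- raw[raw$well == w, ]
    pre <- sort(rows$time_min[rows$phase == "pre"])
    if (!identical(pre, c(0, 3, 6, 9)))
      stop("well ", w, ": pre-enzyme reads must be exactly at 0, 3, 6, 9 min")
    post <- rows$time_min[rows$phase == "post"]
    if (length(post) != 1L || post <= 9)
      stop("well ", w, ": expected a single post-enzyme read later than 9 min")
  }

  lay <- unique(raw[c("well", "sample_id", "role", "dose", "replicate")])
  if (anyDuplicated(lay$well))
    stop("well(s) with inconsistent annotation: ",
         paste(unique(lay$well[duplicated(lay$well)]), collapse = ", "))
  list(layout = plate_layout(lay),
       records = raw[c("well", "time_min", "phase", "absorbance")],
       flagged = flagged)
}

# deterministic CSV writer: fixed number formats, no quoting surprises
write_table_csv <- function(df, path, formats = character()) {
  cols <- lapply(names(df), function(nm) {
    x <- df[[nm]]
    if (is.numeric(x)) {
      fmt <- if (nm %in% names(formats)) formats[[nm]] else "%.6g"
      out <- ifelse(is.na(x), "NA", sprintf(fmt, x))
      out
    } else {
      x <- as.character(x)
      ifelse(is.na(x), "NA", x)
    }
  })
  lines <- c(paste(names(df), collapse = ","),
             if (nrow(df)) do.call(paste, c(cols, sep = ",")))
  con <- file(path, open = "wb") # "wb": identical bytes on every platform
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}

#' Write result tables to a directory
#'
#' Writes each table of a named list as `<name>.csv` with deterministic
#' column order and fixed number formatting, so rewriting identical inputs
#' yields byte-identical files. Empty tables produce header-only files.
#'
#' @param tables named list of data frames.
#' @param dir output directory (created if needed).
#' @param formats optional named character vector of `sprintf` formats per
#'   column name (default `%.6g`).
#' @return Invisibly, the vector of file paths.
#' @export
write_results <- function(tables, dir, formats = character()) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables),
            all(nzchar(names(tables))))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", dir)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write_table_csv(as.data.frame(tables[[nm]]), p, formats = formats)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a result table written by [write_results()]
#'
#' @param path CSV path.
#' @return A data frame; numeric-looking columns are converted.
#' @export
read_result_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read an IC ladder CSV
#'
#' Expects columns `agent`, `level`, `ic`; returns an `ic_ladder` data
#' frame (possibly covering several agents).
#'
#' @param path CSV path.
#' @return An `ic_ladder` data frame.
#' @export
read_ladder_csv <- function(path) {
  df <- read_result_csv(path)
  miss <- setdiff(c("agent", "level", "ic"), names(df))
  if (length(miss))
    stop("ladder CSV is missing column(s): ", paste(miss, collapse = ", "))
  class(df) <- c("ic_ladder", "data.frame")
  df
}

#' Read a YAML run configuration
#'
#' Loads a YAML file of run parameters and overlays explicit overrides
#' (overrides win, mirroring command-line-over-config precedence). The
#' merged list carries an `echo` attribute with one `key: value` line per
#' effective parameter, suitable for logging.
#'
#' @param path YAML file path, or `NULL` for an empty base.
#' @param overrides named list of parameter overrides.
#' @return Named list of effective parameters.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  base <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("no such config file: ", path)
    yaml::read_yaml(path)
  }
  if (length(overrides)) {
    stopifnot(length(names(overrides)) == length(overrides))
    base[names(overrides)] <- overrides
  }
  attr(base, "echo") <- if (length(base))
    paste0(names(base), ": ", vapply(base, function(v)
      paste(format(v), collapse = " "), character(1)))
  else character(0)
  base
}
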