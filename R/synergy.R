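#' Build a fixed-partner combination design
#'
#' The screening combination design varies one agent through a 1:1 serial
#' dilution while each partner is held at a fixed dose equal to its own
#' IC30 (taken from the partner's single-agent IC ladder).
#'
#' @param varied_ladder `ic_ladder` of the varied agent (used for naming).
#' @param partner_ladders list of `ic_ladder`s, one per fixed partner; each
#'   must contain level 30.
#' @param start_dose top dose of the varied agent's dilution, µg/mL.
#' @param n_steps number of 1:1 dilution steps.
#' @param partner_level effect level defining the fixed dose (default 30).
#' @return An object of class `"combination_design"`: list with `varied`
#'   (agent id), `dilution` (strictly halving dose vector) and
#'   `fixed_partners` (data frame: agent, dose, level).
#' @examples
#' berb <- build_ladder(fourpl(1.48, 1.292, name = "berberine"))
#' copt <- build_ladder(fourpl(1.27, 2.936, name = "coptisine"))
#' build_design(berb, list(copt), start_dose = 10, n_steps = 8)
#' @export
build_design <- function(varied_ladder, partner_ladders, start_dose,
                         n_steps = 8, partner_level = 30) {
  stopifnot(is.data.frame(varied_ladder), is.list(partner_ladders),
            start_dose > 0, n_steps >= 1)
  fixed <- lapply(partner_ladders, function(lad) {
    if (!partner_level %in% lad$level)
      stop("partner ladder", if (!is.null(lad$agent))
             paste0(" '", lad$agent[1], "'"),
           " has no IC", partner_level, " entry")
    data.frame(agent = lad$agent[1],
               dose = ladder_ic(lad, partner_level),
               level = partner_level, stringsAsFactors = FALSE)
  })
  fixed <- do.call(rbind, fixed)
  if (any(fixed$dose <= 0)) stop("fixed partner doses must be positive")
  structure(list(
    varied = varied_ladder$agent[1],
    dilution = start_dose / 2^(0:(n_steps - 1)),
    fixed_partners = fixed
  ), class = "combination_design")
}

#' @export
print.combination_design <- function(x, ...) {
  cat("Combination design: varied", x$varied, "over",
      length(x$dilution), "1:1 steps from", max(x$dilution), "ug/mL\n")
  cat("fixed partners:\n")
  print(x$fixed_partners)
  invisible(x)
}

#' Combination index at one effect level (fixed-dose convention)
#'
#' Fractional-effect (FE) sum for a fixed-partner design at one effect
#' level x:
#' \deqn{CI = \frac{IC_x(combo)}{IC_x(varied\ alone)} +
#'   \sum_j \frac{IC_x(combo)}{d_j}}
#' where `IC_x(combo)` is the varied agent's concentration reaching effect
#' x in the combination and `d_j` is partner j's fixed dose (its IC30 in
#' the standard design). This fixed-dose denominator is the convention that
#' reproduces published worked examples of this design; the classical
#' iso-effective Loewe sum is available as [compute_classical_fic()].
#'
#' @param ic_combo varied agent's concentration at effect x in the
#'   combination, µg/mL, > 0.
#' @param ic_alone_varied varied agent's single-agent concentration at the
#'   same effect x, > 0.
#' @param fixed_doses fixed partner doses, each > 0 (possibly empty).
#' @param level optional effect level annotation.
#' @return List of class `"fic_result"`: `level`, `ic_combo`, `fe_varied`,
#'   `fe_fixed` (one per partner), `ci`.
#' @examples
#' compute_ci(0.59, 2.02, 0.95)$ci  # 0.913
#' @export
compute_ci <- function(ic_combo, ic_alone_varied, fixed_doses = numeric(),
                       level = NA_real_) {
  stopifnot(length(ic_combo) == 1L, length(ic_alone_varied) == 1L)
  vals <- c(ic_combo, ic_alone_varied, fixed_doses)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all concentrations and doses must be positive and finite")
  fe_varied <- ic_combo / ic_alone_varied
  fe_fixed <- if (length(fixed_doses)) ic_combo / fixed_doses else numeric(0)
  structure(list(level = level, ic_combo = ic_combo,
                 fe_varied = fe_varied, fe_fixed = fe_fixed,
                 ci = fe_varied + sum(fe_fixed)),
            class = "fic_result")
}

#' @export
print.fic_result <- function(x, digits = 3, ...) {
  cat("FIC/combination index",
      if (!is.na(x$level)) paste0(" at IC", x$level), ": ",
      signif(x$ci, digits), "\n", sep = "")
  cat("  FE(varied) =", signif(x$fe_varied, digits))
  if (length(x$fe_fixed))
    cat("  FE(fixed) =", paste(signif(x$fe_fixed, digits), collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Classical Loewe fractional inhibitory concentration index
#'
#' The textbook iso-effective form: doses in the combination at effect x
#' divided by the corresponding single-agent doses at the same effect x,
#' summed. Equals 1 for any sham combination (an agent against itself) and
#' recovers the generator's interaction index tau on Loewe-simulated data.
#'
#' @param d doses in the combination at the effect level, each > 0.
#' @param D matching single-agent doses at the same effect level, each > 0.
#' @return The FIC index, a positive scalar.
#' @examples
#' compute_classical_fic(c(0.5, 0.5), c(1, 1))  # sham split: exactly 1
#' @export
compute_classical_fic <- function(d, D) {
  if (length(d) != length(D) || !length(d))
    stop("'d' and 'D' must be non-empty vectors of equal length")
  if (any(!is.finite(c(d, D))) || any(c(d, D) <= 0))
    stop("all doses must be positive and finite")
  sum(d / D)
}

# interval scheme: label i applies up to breaks[i] (closed if right_closed),
# last label covers the remainder of (0, Inf)
.fic_schemes <- list(
  schelz = list(
    breaks = c(0.5, 1, 4),
    right_closed = c(TRUE, TRUE, FALSE),
    labels = c("synergy", "additive", "indifferent", "antagonism")
  ),
  berenbaum = list(
    breaks = c(1, 1),
    right_closed = c(FALSE, TRUE),
    labels = c("synergy", "additive", "antagonism")
  ),
  table3_bold = list(
    breaks = 1,
    right_closed = FALSE,
    labels = c("synergy", "no synergy")
  )
)

#' Available FIC classification schemes
#'
#' Three named threshold schemes are shipped. `"schelz"` (the default used
#' for reporting): CI <= 0.5 synergy, 0.5 < CI <= 1 additive,
#' 1 < CI < 4 indifferent, CI >= 4 antagonism. `"berenbaum"`: CI < 1
#' synergy, CI = 1 additive, CI > 1 antagonism (the published wording
#' overlaps at 1.0; the boundary is assigned to "additive" here).
#' `"table3_bold"`: the bold-cell convention, synergy iff CI < 1. Every
#' scheme partitions the positive reals: each CI receives exactly one
#' label.
#'
#' @return Character vector of scheme names.
#' @export
fic_schemes <- function() names(.fic_schemes)

#' Classify a combination index under a named scheme
#'
#' @param ci positive combination-index value(s).
#' @param scheme scheme name; see [fic_schemes()].
#' @return Character vector of labels, same length as `ci`.
#' @examples
#' classify(c(0.43, 0.91, 2, 5), "schelz")
#' @export
classify <- function(ci, scheme = "schelz") {
  if (!scheme %in% names(.fic_schemes))
    stop("unknown scheme '", scheme, "'; available: ",
         paste(names(.fic_schemes), collapse = ", "))
  if (any(!is.finite(ci)) || any(ci <= 0))
    stop("'ci' values must be positive and finite")
  s <- .fic_schemes[[scheme]]
  vapply(ci, function(v) {
    for (i in seq_along(s$breaks)) {
      hit <- if (s$right_closed[i]) v <= s$breaks[i] else v < s$breaks[i]
      if (hit) return(s$labels[i])
    }
    s$labels[length(s$labels)]
  }, character(1))
}

#' Per-level FIC table for a fixed-partner combination
#'
#' Joins the combination ladder (varied agent's IC10..IC90 measured with
#' partners present) against the varied agent's single-agent ladder,
#' computes FE terms and the CI at every shared level, and classifies each
#' CI under the requested schemes.
#'
#' @param combo_ladder `ic_ladder` of the varied agent in combination.
#' @param alone_ladder `ic_ladder` of the varied agent alone.
#' @param fixed_doses named or unnamed vector of fixed partner doses.
#' @param schemes classification scheme names to apply.
#' @return Data frame with one row per level: `level`, `ic_combo`,
#'   `ic_alone`, `fe_varied`, `fe_fixed_*`, `ci` and one label column per
#'   scheme.
#' @export
fic_table <- function(combo_ladder, alone_ladder, fixed_doses,
                      schemes = "schelz") {
  levels <- intersect(combo_ladder$level, alone_ladder$level)
  if (!length(levels)) stop("ladders share no effect levels")
  levels <- sort(levels)
  rows <- lapply(levels, function(x) {
    r <- compute_ci(ladder_ic(combo_ladder, x), ladder_ic(alone_ladder, x),
                    fixed_doses, level = x)
    fe <- r$fe_fixed
    names(fe) <- if (!is.null(names(fixed_doses)) &&
                     all(nzchar(names(fixed_doses))))
      paste0("fe_", names(fixed_doses))
    else paste0("fe_fixed_", seq_along(fe))
    cbind(data.frame(level = x, ic_combo = r$ic_combo,
                     ic_alone = ladder_ic(alone_ladder, x),
                     fe_varied = r$fe_varied),
          as.data.frame(as.list(fe)),
          data.frame(ci = r$ci))
  })
  out <- do.call(rbind, rows)
  for (s in schemes) out[[s]] <- classify(out$ci, s)
  rownames(out) <- NULL
  out
}

#' Isobologram coordinates at one effect level
#'
#' Normalizes an iso-effective dose pair onto fractional axes: for each
#' observation, `fe_a = d_a / D_a` and `fe_b = d_b / D_b` where `D` are the
#' single-agent doses at the effect level. The additivity (Loewe) line is
#' `fe_a + fe_b = 1`; points strictly below it have classical FIC < 1
#' (synergy side). A sham combination lands exactly on the line. With no
#' partner the output degenerates to the `fe_a` axis and is flagged.
#'
#' @param d_varied varied-agent dose(s) in combination at the level.
#' @param D_varied varied agent's single-agent dose at the level.
#' @param d_fixed partner dose(s) (scalar or vector matching `d_varied`);
#'   may be empty for the degenerate single-axis case.
#' @param D_fixed partner's single-agent dose at the level.
#' @return Data frame with `fe_a`, `fe_b`, `fic`; attribute
#'   `additivity_line` gives the line's intercepts, attribute `degenerate`
#'   marks the partnerless case.
#' @export
isobologram_points <- function(d_varied, D_varied, d_fixed = numeric(),
                               D_fixed = numeric()) {
  stopifnot(length(d_varied) >= 1L, length(D_varied) == 1L, D_varied > 0)
  if (any(d_varied <= 0)) stop("combination doses must be positive")
  fe_a <- d_varied / D_varied
  if (!length(d_fixed)) {
    out <- data.frame(fe_a = fe_a, fe_b = 0, fic = fe_a)
    attr(out, "degenerate") <- TRUE
  } else {
    stopifnot(length(D_fixed) == 1L, D_fixed > 0, all(d_fixed > 0))
    fe_b <- rep_len(d_fixed / D_fixed, length(fe_a))
    out <- data.frame(fe_a = fe_a, fe_b = fe_b, fic = fe_a + fe_b)
    attr(out, "degenerate") <- FALSE
  }
  attr(out, "additivity_line") <- c(x_intercept = 1, y_intercept = 1)
  out
}

#' Plot an isobologram
#'
#' @param points result of [isobologram_points()].
#' @param xlab,ylab axis labels.
#' @param ... passed to [graphics::plot()].
#' @export
plot_isobologram <- function(points, xlab = "FE (varied)",
                             ylab = "FE (fixed)", ...) {
  lim <- max(1, points$fe_a, points$fe_b) * 1.05
  graphics::plot(points$fe_a, points$fe_b, xlim = c(0, lim),
                 ylim = c(0, lim), xlab = xlab, ylab = ylab, ...)
  graphics::segments(0, 1, 1, 0, lty = 2)
  invisible(points)
}
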