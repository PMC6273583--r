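#' Four-parameter logistic dose-response model
#'
#' Constructs a 4PL model object describing percent effect as a function of
#' dose:
#' \deqn{E(d) = bottom + (top - bottom) \frac{d^h}{d^h + IC_{50}^h}}
#' with the effect ascending from `bottom` at dose 0 towards `top` at
#' saturating dose and passing exactly through `(bottom + top)/2` at
#' `d = ic50`. This is the parameterization used throughout the package for
#' percent-inhibition curves; viability (descending) curves are handled by
#' the `decreasing` flag of [fit_4pl()].
#'
#' @param ic50 curve midpoint, in µg/mL; must be positive.
#' @param hill dimensionless slope parameter; must be positive (the curve is
#'   then strictly increasing in dose between the asymptotes).
#' @param bottom,top lower and upper asymptotes in percent effect; must
#'   satisfy `bottom < top`. Defaults 0 and 100, the fixed-asymptote form
#'   used for screening samples.
#' @param name optional label (e.g. the agent name) carried into printed
#'   output and ladders.
#'
#' @return An object of class `"fourpl"`.
#' @seealso [fit_4pl()], [ic_at_level()], [build_ladder()],
#'   [fourpl_from_ladder()]
#' @examples
#' berb <- fourpl(ic50 = 1.48, hill = 1.292, name = "berberine")
#' predict(berb, dose = 1.48)  # exactly 50
#' ic_at_level(berb, 70)
#' @export
fourpl <- function(ic50, hill, bottom = 0, top = 100, name = NULL) {
  stopifnot(is.numeric(ic50), length(ic50) == 1L, is.finite(ic50),
            is.numeric(hill), length(hill) == 1L, is.finite(hill),
            is.numeric(bottom), length(bottom) == 1L, is.finite(bottom),
            is.numeric(top), length(top) == 1L, is.finite(top))
  if (ic50 <= 0) stop("'ic50' must be positive, got ", ic50)
  if (hill <= 0) stop("'hill' must be positive (non-monotone models are not supported), got ", hill)
  if (bottom >= top) stop("'bottom' must be strictly less than 'top'")
  structure(
    list(bottom = bottom, top = top, ic50 = ic50, hill = hill, name = name),
    class = "fourpl"
  )
}

#' @export
print.fourpl <- function(x, digits = 4, ...) {
  cat("Four-parameter logistic model",
      if (!is.null(x$name)) paste0(" (", x$name, ")"), "\n", sep = "")
  print(signif(coef(x), digits))
  invisible(x)
}

#' @export
coef.fourpl <- function(object, ...) {
  c(bottom = object$bottom, top = object$top,
    ic50 = object$ic50, hill = object$hill)
}

# core forward curve; vectorized over dose, exact at dose 0
fourpl_effect <- function(bottom, top, ic50, hill, dose, decreasing = FALSE) {
  q <- ifelse(dose == 0, 0, 1 / (1 + (ic50 / dose)^hill))
  if (decreasing) top - (top - bottom) * q else bottom + (top - bottom) * q
}

#' Predict percent effect from a 4PL model
#'
#' @param object a [fourpl()] model.
#' @param newdata optional `data.frame` with a `dose` column.
#' @param dose alternatively, a numeric vector of doses (µg/mL), all >= 0.
#' @param ... unused.
#' @return Numeric vector of percent effects in `[bottom, top]`.
#' @export
predict.fourpl <- function(object, newdata = NULL, dose = NULL, ...) {
  if (is.null(dose)) {
    if (is.null(newdata) || is.null(newdata$dose))
      stop("supply 'dose' or 'newdata' with a dose column")
    dose <- newdata$dose
  }
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("doses must be finite and non-negative")
  fourpl_effect(object$bottom, object$top, object$ic50, object$hill, dose)
}

#' Invert a 4PL curve to the concentration producing a given percent effect
#'
#' Closed-form inversion of the four-parameter logistic:
#' \deqn{IC_x = IC_{50} \left(\frac{x - bottom}{top - x}\right)^{1/h}}
#' strictly increasing in `x` on `(bottom, top)`.
#'
#' @param object a [fourpl()] model or [fit_4pl()] fit.
#' @param level percent effect level(s), each strictly inside
#'   `(bottom, top)`.
#' @return Concentration(s) in µg/mL, same length as `level`.
#' @examples
#' ic_at_level(fourpl(ic50 = 1.48, hill = 1.292), c(10, 50, 90))
#' @export
ic_at_level <- function(object, level) {
  stopifnot(inherits(object, "fourpl"))
  if (any(!is.finite(level)))
    stop("effect levels must be finite")
  bad <- level <= object$bottom | level >= object$top
  if (any(bad))
    stop("effect level(s) ", paste(level[bad], collapse = ", "),
         " outside the achievable open range (", object$bottom, ", ",
         object$top, ")")
  object$ic50 *
    ((level - object$bottom) / (object$top - level))^(1 / object$hill)
}

#' Build an IC ladder (IC10..IC90) from a 4PL model
#'
#' Tabulates the concentrations producing each requested percent effect by
#' closed-form inversion. The returned ladder is the standard row object for
#' fixed-partner combination designs: the partner's IC30 entry becomes its
#' fixed dose, and per-level combination indices are computed ladder against
#' ladder.
#'
#' @param object a [fourpl()] model or fit.
#' @param levels percent effect levels; default `seq(10, 90, by = 10)`.
#' @return A `data.frame` of class `"ic_ladder"` with columns `agent`,
#'   `level`, `ic` (µg/mL), strictly increasing in `level`.
#' @export
build_ladder <- function(object, levels = seq(10, 90, by = 10)) {
  stopifnot(inherits(object, "fourpl"))
  if (anyDuplicated(levels)) stop("duplicate effect levels requested")
  bad <- levels <= object$bottom | levels >= object$top
  if (any(bad))
    stop("cannot build ladder: level(s) ", paste(levels[bad], collapse = ", "),
         " outside achievable range (", object$bottom, ", ", object$top, ")")
  levels <- sort(levels)
  ic <- ic_at_level(object, levels)
  if (any(diff(ic) <= 0)) # cannot happen for a valid model; guard regardless
    stop("ladder concentrations are not strictly increasing")
  out <- data.frame(
    agent = if (is.null(object$name)) NA_character_ else object$name,
    level = levels, ic = ic, stringsAsFactors = FALSE
  )
  class(out) <- c("ic_ladder", "data.frame")
  out
}

#' Extract one level's concentration from an IC ladder
#'
#' @param ladder an `ic_ladder` data frame (or any data frame with `level`
#'   and `ic` columns).
#' @param level a single percent effect level that must be present.
#' @return The concentration in µg/mL.
#' @export
ladder_ic <- function(ladder, level) {
  stopifnot(is.data.frame(ladder), length(level) == 1L)
  i <- which(ladder$level == level)
  if (length(i) != 1L)
    stop("level ", level, " not present (once) in ladder",
         if (!is.null(ladder$agent[1]) && !is.na(ladder$agent[1]))
           paste0(" for ", ladder$agent[1]))
  ladder$ic[i]
}

#' Solve the Hill slope from two IC-ladder entries
#'
#' For a 0-100 logistic, two effect levels pin the slope:
#' \deqn{h = \frac{logit(x_2) - logit(x_1)}{\log IC_{x_2} - \log IC_{x_1}}}
#' with `logit(x) = log((x - bottom)/(top - x))`. For the canonical
#' (IC10, IC90) pair this reduces to `h = log(81) / log(IC90/IC10)`.
#'
#' @param ic_lo,ic_hi concentrations at the lower and higher effect level.
#' @param level_lo,level_hi the two percent effect levels (defaults 10, 90).
#' @param bottom,top asymptotes (defaults 0, 100).
#' @return The Hill slope (dimensionless, positive).
#' @export
hill_from_ic_pair <- function(ic_lo, ic_hi, level_lo = 10, level_hi = 90,
                              bottom = 0, top = 100) {
  stopifnot(ic_lo > 0, ic_hi > 0, level_lo < level_hi,
            bottom < level_lo, level_hi < top)
  if (ic_hi <= ic_lo)
    stop("IC at the higher level must exceed IC at the lower level")
  lgt <- function(x) log((x - bottom) / (top - x))
  (lgt(level_hi) - lgt(level_lo)) / (log(ic_hi) - log(ic_lo))
}

#' Reconstruct a 0-100 4PL model from two ladder entries
#'
#' Solves the Hill slope from the outer pair of a printed or computed IC
#' ladder ([hill_from_ic_pair()]) and inverts to the midpoint,
#' `IC50 = IC_lo * ((50 - bottom)/(top - 50) / ((lo - bottom)/(top - lo)))^(1/h)`.
#' Used both to parameterize synthetic agents from published ladders and as
#' the ladder-consistency check on single-agent rows.
#'
#' @param ladder an `ic_ladder` data frame, or `NULL` if `ic_lo`/`ic_hi`
#'   given directly.
#' @param level_lo,level_hi which two levels to use (defaults 10 and 90).
#' @param ic_lo,ic_hi concentrations, taken from `ladder` when omitted.
#' @param bottom,top asymptotes, default 0 and 100.
#' @param name optional agent name (defaults to the ladder's).
#' @return A [fourpl()] model.
#' @examples
#' # slope and midpoint implied by a printed (IC10, IC90) = (0.27, 8.09) pair
#' m <- fourpl_from_ladder(ic_lo = 0.27, ic_hi = 8.09)
#' coef(m)["ic50"]
#' @export
fourpl_from_ladder <- function(ladder = NULL, level_lo = 10, level_hi = 90,
                               ic_lo = NULL, ic_hi = NULL,
                               bottom = 0, top = 100, name = NULL) {
  if (!is.null(ladder)) {
    if (is.null(ic_lo)) ic_lo <- ladder_ic(ladder, level_lo)
    if (is.null(ic_hi)) ic_hi <- ladder_ic(ladder, level_hi)
    if (is.null(name) && !is.null(ladder$agent)) name <- ladder$agent[1]
  }
  if (is.null(ic_lo) || is.null(ic_hi))
    stop("supply a ladder or both 'ic_lo' and 'ic_hi'")
  h <- hill_from_ic_pair(ic_lo, ic_hi, level_lo, level_hi, bottom, top)
  ic50 <- ic_lo * (((50 - bottom) / (top - 50)) /
                     ((level_lo - bottom) / (top - level_lo)))^(1 / h)
  fourpl(ic50 = ic50, hill = h, bottom = bottom, top = top, name = name)
}
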