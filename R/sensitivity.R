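# Monotonicity and slope-based sensitivity classification of family curves
# (burst characteristic versus conductance fraction).

#' Monotonicity of a family curve
#'
#' Sign test on consecutive differences of the characteristic values along
#' the family sequence.  Ties (zero differences) are compatible with either
#' direction; an entirely flat curve is reported as increasing.
#'
#' @param y Characteristic values ordered by the defining-parameter value
#'   (length at least 2).
#' @return `"increasing"`, `"decreasing"` or `"non_monotonic"`.
#' @examples
#' curve_monotonicity(c(12, 10, 7, 5))
#' curve_monotonicity(c(5, 7, 6))
#' @export
curve_monotonicity <- function(y) {
  if (length(y) < 2) abort("Need at least 2 points.")
  d <- diff(y)
  if (all(d >= 0)) "increasing"
  else if (all(d <= 0)) "decreasing"
  else "non_monotonic"
}

# Minimum of the derivative of a fitted polynomial over [x1, xn]: evaluated
# on a 1,000-point grid plus the analytic critical points of the derivative
# and the endpoints.  Deterministic.
min_poly_slope <- function(coefs, xr) {
  dp <- pracma::polyder(coefs)
  xs <- seq(xr[1], xr[2], length.out = 1000)
  if (length(dp) > 1) {
    ddp <- pracma::polyder(dp)
    if (length(ddp) >= 2) {
      roots <- polyroot(rev(ddp))
      re <- Re(roots)[abs(Im(roots)) < 1e-8]
      xs <- c(xs, re[re >= xr[1] & re <= xr[2]])
    }
  }
  min(pracma::polyval(dp, xs))
}

#' Slope-based sensitivity class of a family curve
#'
#' Fits a polynomial of degree `min(5, points - 1)` to the characteristic
#' values against the conductance fraction (x in canonical-fraction units,
#' 0-1.75; y in seconds or Hz), takes the most negative tangent slope of the
#' fit over the family span, and classifies: high sensitivity at slope
#' `<= -2.5` (decline steeper than about 68 degrees), low at `>= -0.4`
#' (shallower than about 22 degrees), medium otherwise.  For exactly linear
#' curves the fitted slope equals the analytic slope.
#'
#' @param x Member fractions, non-decreasing (duplicated points are
#'   dropped); at least 3 distinct points.
#' @param y Characteristic values, same length.
#' @param thresholds `c(high, low)` slope thresholds; default
#'   `c(-2.5, -0.4)`.
#' @return A one-row tibble: `class` (`"high"`/`"medium"`/`"low"`),
#'   `max_descent_slope`, `degree`, `monotonic`.
#' @examples
#' classify_curve(seq(0, 1.75, 0.25), 12 - 4 * seq(0, 1.75, 0.25))
#' @export
classify_curve <- function(x, y, thresholds = c(-2.5, -0.4)) {
  keep <- !duplicated(x)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("Curve too short to fit (need 3 points).")
  if (any(diff(x) <= 0)) abort("`x` must be increasing.")
  degree <- min(5, length(x) - 1)
  coefs <- pracma::polyfit(x, y, degree)
  slope <- min_poly_slope(coefs, range(x))
  cls <- if (slope <= thresholds[1]) "high"
  else if (slope >= thresholds[2]) "low"
  else "medium"
  tibble(class = cls, max_descent_slope = slope, degree = degree,
         monotonic = curve_monotonicity(y))
}

#' Classify family curves of a burst characteristic
#'
#' Builds, for every family with at least 3 members, the characteristic
#' versus defining-fraction curve from a labeled database and classifies its
#' period sensitivity with [classify_curve()].
#'
#' @param families An [build_families()] result.
#' @param db Instance database holding the characteristic for every member
#'   point.
#' @param characteristic Column name of the characteristic (default
#'   `"period_s"`).
#' @return An object of class `hco_sensitivity`: `families` (rows with at
#'   least 3 members) with added list-columns `x`, `y` and columns `class`,
#'   `max_descent_slope`, `monotonic`.
#' @export
classify_family_curves <- function(families, db,
                                   characteristic = "period_s") {
  defining <- families$defining[1]
  eligible <- filter(families, .data$n_members >= 3)
  if (nrow(eligible) == 0) {
    out <- mutate(eligible, x = list(), y = list(),
                  class = character(), max_descent_slope = double(),
                  monotonic = character())
    class(out) <- c("hco_sensitivity", class(out))
    return(out)
  }
  lookup <- select(db, all_of(.hco_params), all_of(characteristic))
  curves <- map(seq_len(nrow(eligible)), function(i) {
    fam <- eligible[i, ]
    pts <- tibble(!!defining := fam$members[[1]])
    for (p in setdiff(.hco_params, defining)) pts[[p]] <- fam[[p]]
    hit <- left_join(pts, lookup, by = .hco_params)
    if (anyNA(hit[[characteristic]])) {
      abort(paste0("Characteristic missing for a member of family ",
                   fam$context_key))
    }
    list(x = pts[[defining]], y = hit[[characteristic]])
  })
  cl <- map(curves, function(cv) classify_curve(cv$x, cv$y))
  out <- eligible |>
    mutate(x = map(curves, "x"), y = map(curves, "y"),
           class = map_chr(cl, function(d) d$class),
           max_descent_slope = map_dbl(cl, function(d) d$max_descent_slope),
           monotonic = map_chr(cl, function(d) d$monotonic))
  class(out) <- c("hco_sensitivity", class(out))
  out
}

#' Average change of a characteristic across families
#'
#' Mean over families of the difference between the last and first members'
#' characteristic values; a decreasing characteristic yields a negative
#' value.
#'
#' @param curves A list of curves (each with `y`), an `hco_sensitivity`
#'   tibble, or a list-column of y-vectors.
#' @return A single number.
#' @examples
#' average_change(list(list(y = c(12, 9)), list(y = c(10, 5))))
#' @export
average_change <- function(curves) {
  ys <- if (is.data.frame(curves)) curves$y else map(curves, "y")
  if (length(ys) == 0) abort("Need at least one curve.")
  mean(map_dbl(ys, function(y) y[length(y)] - y[1]))
}

#' Parameter summaries per sensitivity class
#'
#' For every sensitivity class and every context parameter (the seven other
#' conductance fractions and the leak reversal), tallies how many distinct
#' families sit at each grid value and computes the median value.
#'
#' @param classified An [classify_family_curves()] result.
#' @return A list of tibbles: `counts` (`class`, `parameter`, `value`, `n`)
#'   and `medians` (`class`, `parameter`, `median`).
#' @export
sensitivity_group_summary <- function(classified) {
  defining <- classified$defining[1]
  params <- setdiff(.hco_params, defining)
  long <- classified |>
    select("class", all_of(params)) |>
    tidyr::pivot_longer(all_of(params), names_to = "parameter",
                        values_to = "value")
  counts <- count(long, .data$class, .data$parameter, .data$value,
                  name = "n")
  medians <- long |>
    group_by(.data$class, .data$parameter) |>
    summarise(median = stats::median(.data$value), .groups = "drop")
  list(counts = counts, medians = medians)
}
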