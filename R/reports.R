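# Group-level summaries: the 3D projection / pie composition and the
# per-parameter period histograms with skewness.

#' Project a group onto three parameters with pie composition
#'
#' Groups instances by the values of three chosen parameters; each occupied
#' point in that 3D space records its instance count, the composition over a
#' fourth parameter (the pie slices), and a display radius equal to the
#' natural logarithm of the count.
#'
#' @param db Tibble of instances (e.g. the realistic-HCO group).
#' @param axes Character vector of three distinct parameter names.
#' @param pie_param A fourth, distinct parameter whose value composition is
#'   tallied per point.
#' @return Tibble with the three axis columns, `count`, `radius`
#'   (`log(count)`) and a `composition` list-column of
#'   (`value`, `n`) tibbles summing to `count`.
#' @examples
#' db <- make_synthetic_db(grid_spec(fractions = c(0.75, 1.25),
#'                                   e_leak_levels = c(-60, -55)), seed = 1)
#' projection_pies(dplyr::filter(db, label == "rHCO"))
#' @export
projection_pies <- function(db, axes = c("x_P", "x_K2", "x_Leak"),
                            pie_param = "e_leak") {
  axes <- map_chr(axes, resolve_param)
  pie_param <- resolve_param(pie_param)
  chosen <- c(axes, pie_param)
  if (length(axes) != 3 || anyDuplicated(chosen)) {
    abort("`axes` must be three distinct parameters, distinct from `pie_param`.")
  }
  db |>
    group_by(across(all_of(axes))) |>
    summarise(count = n(),
              composition = list(count(dplyr::pick(dplyr::everything()),
                                       value = .data[[pie_param]],
                                       name = "n")),
              .groups = "drop") |>
    mutate(radius = log(.data$count))
}

#' Period histograms per parameter value
#'
#' Bins burst periods into one-second integer-edged bins `[n, n+1)` for each
#' value of a chosen parameter.
#'
#' @param db Instance tibble with a `period_s` column (undefined periods are
#'   dropped).
#' @param by Parameter to stratify by (default `"x_h"`).
#' @return Tibble `by_value`, `bin` (left edge), `n`.
#' @export
period_histograms <- function(db, by = "x_h") {
  by <- resolve_param(by)
  db |>
    filter(!is.na(.data$period_s)) |>
    mutate(by_value = .data[[by]], bin = floor(.data$period_s)) |>
    count(.data$by_value, .data$bin, name = "n")
}

#' Sample skewness of periods per parameter value
#'
#' The adjusted Fisher-Pearson standardized third moment (the
#' small-sample-corrected estimator), per value of the stratifying
#' parameter.
#'
#' @inheritParams period_histograms
#' @return Tibble `by_value`, `n`, `skewness` (`NA` for fewer than 3
#'   observations).
#' @export
period_skewness <- function(db, by = "x_h") {
  by <- resolve_param(by)
  db |>
    filter(!is.na(.data$period_s)) |>
    group_by(by_value = .data[[by]]) |>
    summarise(n = n(),
              skewness = if (n() >= 3) {
                e1071::skewness(.data$period_s, type = 2)
              } else NA_real_,
              .groups = "drop")
}
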