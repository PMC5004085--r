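# Family-structure robustness measures and the weighted robustness score.

#' Family-structure robustness measures
#'
#' For a size threshold `n`, computes the three measures built on family
#' structure: `X`, the number of families with more than `n` members; `Y`,
#' the number of noninterrupted families with more than `n` members; and
#' `Z`, the number of missing members of those families whose instance keeps
#' functional HCO activity (label `fHCO`).  By default `Z` counts only
#' interruptions (missing members inside the permissible range); set
#' `z_scope = "all_missing"` to include out-of-range missing members as
#' well.
#'
#' @param size_table An [tabulate_sizes()] result (or any tibble with
#'   `size`, `total`, `noninterrupted`).
#' @param attribution Optional [attribute_missing()] result; without it `Z`
#'   is `NA`.
#' @param n Size threshold, between 0 and the maximum size minus one.
#' @param z_scope `"inside"` (default) or `"all_missing"`.
#' @return One-row tibble with `n`, `X`, `Y`, `Z`.
#' @examples
#' fx <- load_fixture_tables()
#' h_row <- dplyr::filter(fx$table1, param == "h")
#' robustness_measures(h_row, n = 4)
#' @export
robustness_measures <- function(size_table, attribution = NULL, n,
                                z_scope = c("inside", "all_missing")) {
  z_scope <- match.arg(z_scope)
  max_size <- max(size_table$size)
  if (n < 0 || n > max_size - 1) {
    abort(paste0("`n` must be between 0 and ", max_size - 1, "."))
  }
  big <- filter(size_table, .data$size > n)
  x <- sum(big$total)
  y <- sum(big$noninterrupted)
  z <- NA_integer_
  if (!is.null(attribution)) {
    zrows <- filter(attribution, .data$family_size > n,
                    .data$label == "fHCO")
    if (z_scope == "inside") zrows <- filter(zrows, .data$where == "inside")
    z <- nrow(zrows)
  }
  tibble(n = n, X = x, Y = y, Z = z)
}

#' Weighted robustness score
#'
#' The weighted cumulative sum of the three family-structure measures,
#' `R = wX * X + wY * Y + wZ * Z`.  The weights express the relative
#' importance of large families, uninterrupted sequences and
#' activity-preserving interruptions, and must be non-negative and sum to 1.
#'
#' @param X,Y,Z The three measures (see [robustness_measures()]).
#' @param weights Numeric length-3 vector `c(wX, wY, wZ)`; default
#'   `c(0.5, 0.5, 0)`.
#' @return The score `R` (a single number).
#' @examples
#' robustness_score(4669, 1729, 8945)           # 3199
#' robustness_score(53, 51, 2)                  # 52
#' @export
robustness_score <- function(X, Y, Z = 0, weights = c(0.5, 0.5, 0)) {
  if (length(weights) != 3 || any(weights < 0)) {
    abort("`weights` must be three non-negative numbers.")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    abort("`weights` must sum to 1 (within 1e-9).")
  }
  if (weights[3] == 0 && (is.na(Z) || is.null(Z))) Z <- 0
  weights[1] * X + weights[2] * Y + weights[3] * Z
}

#' Normalize a robustness score
#'
#' Expresses the score relative to a user-chosen denominator (e.g. the
#' number of families above the size threshold), reported to three decimals.
#'
#' @param score A [robustness_score()] value.
#' @param denominator Positive number.
#' @return `round(score / denominator, 3)`.
#' @examples
#' normalize_score(3199, 4669)  # 0.685
#' @export
normalize_score <- function(score, denominator) {
  if (!is.numeric(denominator) || denominator <= 0) {
    abort("`denominator` must be positive.")
  }
  round(score / denominator, 3)
}

#' Full robustness report for one parameter
#'
#' Combines measures, score and optional normalization into a one-row
#' report.
#'
#' @inheritParams robustness_measures
#' @inheritParams robustness_score
#' @param parameter Name of the assessed parameter (annotation only).
#' @param normalize `"none"`, `"X"` or `"Y"`: normalize the score by that
#'   measure.
#' @return An object of class `hco_robustness`: a one-row tibble with
#'   `parameter`, `n`, `X`, `Y`, `Z`, `w_X`, `w_Y`, `w_Z`, `R`,
#'   `normalized`.
#' @examples
#' fx <- load_fixture_tables()
#' robustness_report(dplyr::filter(fx$table1, param == "h"), n = 4,
#'                   parameter = "h", normalize = "X")
#' @export
robustness_report <- function(size_table, attribution = NULL, n,
                              weights = c(0.5, 0.5, 0), parameter = NA,
                              z_scope = c("inside", "all_missing"),
                              normalize = c("none", "X", "Y")) {
  normalize <- match.arg(normalize)
  m <- robustness_measures(size_table, attribution, n, z_scope)
  r <- robustness_score(m$X, m$Y, m$Z, weights)
  norm <- switch(normalize, none = NA_real_,
                 X = normalize_score(r, m$X),
                 Y = normalize_score(r, m$Y))
  out <- tibble(parameter = as.character(parameter), n = m$n,
                X = m$X, Y = m$Y, Z = m$Z,
                w_X = weights[1], w_Y = weights[2], w_Z = weights[3],
                R = r, normalized = norm)
  class(out) <- c("hco_robustness", class(out))
  out
}

#' @rdname robustness_report
#' @param x An `hco_robustness` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.hco_robustness <- function(x, ...) {
  tibble(measure = c("X", "Y", "Z"),
         value = c(x$X, x$Y, x$Z),
         weight = c(x$w_X, x$w_Y, x$w_Z))
}

#' @rdname robustness_report
#' @exportS3Method generics::glance
glance.hco_robustness <- function(x, ...) {
  tibble(parameter = x$parameter, n = x$n, R = x$R,
         normalized = x$normalized)
}
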