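#' @importFrom rlang .data abort %||% := hash
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   across all_of left_join bind_rows count n rename relocate distinct pull
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_chr map_int map_lgl map2 pmap imap
#' @importFrom generics tidy glance
NULL

# The eight varied parameters, in the fixed mixed-radix enumeration order
# (slowest-varying first).
.hco_params <- c("x_P", "x_K2", "x_Leak", "x_CaS", "x_h", "x_SynS", "x_SynG",
                 "e_leak")

# Conductance scale fractions only (everything but the leak reversal).
.hco_fractions <- setdiff(.hco_params, "e_leak")

.hco_labels <- c("silent", "spiking", "plateau", "asymmetric", "burster",
                 "realistic_burster", "fHCO", "rHCO", "other")

#' Varied parameters of the HCO grid
#'
#' Names of the eight varied parameters, in the canonical enumeration order:
#' seven maximal-conductance scale fractions (`x_P`, `x_K2`, `x_Leak`,
#' `x_CaS`, `x_h`, `x_SynS`, `x_SynG`) followed by the leak reversal
#' potential `e_leak` (mV).
#'
#' @param fractions_only If `TRUE`, drop `e_leak` and return only the seven
#'   conductance fractions.
#' @return Character vector of parameter names.
#' @export
hco_parameters <- function(fractions_only = FALSE) {
  if (fractions_only) .hco_fractions else .hco_params
}

#' Activity labels recognised in instance tables
#'
#' @return Character vector of the nine activity labels.
#' @export
hco_activity_labels <- function() .hco_labels

#' Canonical maximal conductances and leak reversal potential
#'
#' The canonical parameter set of the two-cell leech heartbeat half-center
#' oscillator model: seven varied maximal conductances, four fixed maximal
#' conductances, and the canonical leak reversal potential.  Grid fractions
#' scale the varied conductances relative to these values.
#'
#' @param ... Named overrides for any canonical value (nS for conductances,
#'   mV for `e_leak`).
#' @return A one-row tibble with columns `g_CaS`, `g_h`, `g_P`, `g_K2`,
#'   `g_Leak`, `g_SynS`, `g_SynG` (varied, nS), `g_Na`, `g_CaF`, `g_K1`,
#'   `g_KA` (fixed, nS) and `e_leak` (mV).
#' @examples
#' canonical_set()
#' canonical_set(g_h = 8)
#' @export
canonical_set <- function(...) {
  canon <- tibble(
    g_CaS = 3.2, g_h = 4, g_P = 7, g_K2 = 80, g_Leak = 8,
    g_SynS = 60, g_SynG = 30,
    g_Na = 200, g_CaF = 5, g_K1 = 100, g_KA = 80,
    e_leak = -60
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(canon))
    if (length(bad)) {
      abort(paste0("Unknown canonical field(s): ", toString(bad)))
    }
    canon[names(dots)] <- dots
  }
  g_cols <- setdiff(names(canon), "e_leak")
  if (any(unlist(canon[g_cols]) < 0)) {
    abort("Canonical conductances must be non-negative.")
  }
  canon
}

#' Define a parameter grid
#'
#' A grid specification holds the ordered list of scale fractions for each of
#' the seven varied maximal conductances and the ordered list of leak
#' reversal potentials.  The defaults are the levels of the full brute-force
#' database: fractions 0 to 1.75 in steps of 0.25 (0% to 175% of canonical)
#' and `e_leak` at -70, -65, -60, -55, -50 mV.
#'
#' @param fractions Numeric vector of scale fractions applied to every varied
#'   conductance, or a named list giving a vector per parameter (names among
#'   `hco_parameters(fractions_only = TRUE)`).
#' @param e_leak_levels Numeric vector of leak reversal potentials (mV).
#' @return An object of class `hco_grid_spec`: a named list of strictly
#'   increasing level vectors, one per varied parameter.
#' @examples
#' spec <- grid_spec()
#' grid_size(spec)
#' grid_spec(fractions = c(0.5, 1, 1.5), e_leak_levels = c(-65, -55))
#' @export
grid_spec <- function(fractions = seq(0, 1.75, by = 0.25),
                      e_leak_levels = c(-70, -65, -60, -55, -50)) {
  if (is.list(fractions)) {
    bad <- setdiff(names(fractions), .hco_fractions)
    if (length(bad)) abort(paste0("Unknown parameter(s): ", toString(bad)))
    levels <- lapply(stats::setNames(.hco_fractions, .hco_fractions),
                     function(p) fractions[[p]] %||% seq(0, 1.75, by = 0.25))
  } else {
    levels <- stats::setNames(rep(list(as.numeric(fractions)),
                                  length(.hco_fractions)), .hco_fractions)
  }
  levels$e_leak <- as.numeric(e_leak_levels)
  for (p in names(levels)) {
    lv <- levels[[p]]
    if (length(lv) == 0) abort(paste0("Empty level list for ", p))
    if (any(!is.finite(lv))) abort(paste0("Non-finite level for ", p))
    if (any(diff(lv) <= 0)) {
      abort(paste0("Levels for ", p, " must be strictly increasing."))
    }
    if (p != "e_leak" && any(lv < 0)) {
      abort(paste0("Fractions for ", p, " must be non-negative."))
    }
  }
  structure(levels[.hco_params], class = "hco_grid_spec")
}

#' @export
print.hco_grid_spec <- function(x, ...) {
  cat("<hco_grid_spec> ", format(grid_size(x), big.mark = ","),
      " points\n", sep = "")
  for (p in names(x)) {
    cat(" ", format(p, width = 7), ": ", paste(x[[p]], collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Number of points in a grid (analytic)
#'
#' The Cartesian-product size, computed from the level counts without
#' instantiating the grid.
#'
#' @param spec A [grid_spec()].
#' @return A double (the full database has 10,485,760 points).
#' @examples
#' grid_size(grid_spec())
#' @export
grid_size <- function(spec) {
  stopifnot(inherits(spec, "hco_grid_spec"))
  prod(map_dbl(spec, length))
}

#' Enumerate all grid points
#'
#' Emits the full Cartesian product of the grid levels exactly once, in
#' mixed-radix order with `x_P` varying slowest and `e_leak` fastest.  Use
#' [grid_size()] when only the count is needed; the default full grid has
#' 10.5 million rows.
#'
#' @param spec A [grid_spec()].
#' @return A tibble with one row per grid point and the eight parameter
#'   columns of [hco_parameters()].
#' @examples
#' enumerate_grid(grid_spec(fractions = c(0, 1), e_leak_levels = -60))
#' @export
enumerate_grid <- function(spec) {
  stopifnot(inherits(spec, "hco_grid_spec"))
  do.call(tidyr::expand_grid, as.list(spec))
}

#' Convert grid fractions to absolute conductances
#'
#' Each varied conductance is its scale fraction times the canonical value;
#' the four fixed conductances are passed through unchanged.
#'
#' @param points A tibble of grid points (columns of [hco_parameters()]).
#' @param canon A [canonical_set()].
#' @return A tibble with absolute conductances `g_P`, `g_K2`, `g_Leak`,
#'   `g_CaS`, `g_h`, `g_SynS`, `g_SynG`, `g_Na`, `g_CaF`, `g_K1`, `g_KA`
#'   (nS) and `e_leak` (mV).
#' @examples
#' to_absolute(tibble::tibble(x_P = 1, x_K2 = 0.75, x_Leak = 1, x_CaS = 1,
#'                            x_h = 1, x_SynS = 0, x_SynG = 0, e_leak = -60))
#' @export
to_absolute <- function(points, canon = canonical_set()) {
  check_point_columns(points)
  tibble(
    g_P    = points$x_P    * canon$g_P,
    g_K2   = points$x_K2   * canon$g_K2,
    g_Leak = points$x_Leak * canon$g_Leak,
    g_CaS  = points$x_CaS  * canon$g_CaS,
    g_h    = points$x_h    * canon$g_h,
    g_SynS = points$x_SynS * canon$g_SynS,
    g_SynG = points$x_SynG * canon$g_SynG,
    g_Na   = canon$g_Na, g_CaF = canon$g_CaF,
    g_K1   = canon$g_K1, g_KA  = canon$g_KA,
    e_leak = points$e_leak
  )
}

check_point_columns <- function(points, where = "points") {
  missing <- setdiff(.hco_params, names(points))
  if (length(missing)) {
    abort(paste0("Missing parameter column(s) in ", where, ": ",
                 toString(missing)))
  }
  invisible(points)
}

#' Resolve a defining-parameter name
#'
#' Accepts either a full column name (`"x_h"`) or the short conductance name
#' (`"h"`); `e_leak` only by its full name.
#' @noRd
resolve_param <- function(defining) {
  if (length(defining) != 1 || !is.character(defining)) {
    abort("`defining` must be a single parameter name.")
  }
  if (defining %in% .hco_params) return(defining)
  full <- paste0("x_", defining)
  if (full %in% .hco_params) return(full)
  abort(paste0("Unknown parameter: ", defining,
               ". Expected one of: ", toString(.hco_params)))
}

#' Context key for one-parameter families
#'
#' Two grid points receive the same key exactly when they agree on all varied
#' parameters except the defining one.  The key is a string built from the
#' seven non-defining values printed to two decimals (fractions) or as whole
#' millivolts (`e_leak`), so grouping is exact.
#'
#' @param points A tibble of grid points.
#' @param defining Name of the defining parameter (`"x_h"` or `"h"` style).
#' @return Character vector of keys, one per row of `points`.
#' @examples
#' pts <- enumerate_grid(grid_spec(fractions = c(0, 1), e_leak_levels = -60))
#' context_key(pts, "h")
#' @export
context_key <- function(points, defining) {
  defining <- resolve_param(defining)
  check_point_columns(points)
  others <- setdiff(.hco_params, defining)
  cols <- map(others, function(p) {
    if (p == "e_leak") sprintf("%.0f", points[[p]])
    else sprintf("%.2f", points[[p]])
  })
  keyed <- do.call(paste, c(list(sep = "|"),
                            map2(others, cols, function(p, v) paste0(p, "=", v))))
  keyed
}

# ---- instance table (TSV) ---------------------------------------------------

.db_header <- "# hcofam instance table v1"
.db_cols <- c(.hco_fractions, "e_leak_mV", "label", "period_s",
              "spike_freq_hz", "duty_pct", "phase", "cv_period", "cv_amp",
              "fail_flags")

#' Write an instance table
#'
#' Serializes instance records to a versioned tab-separated file: one row per
#' grid point with its parameters, activity label, burst characteristics and
#' failed-criteria mask.  Characteristics that are undefined for a label
#' (e.g. period of a silent instance) are written as empty fields.
#'
#' @param records Tibble of instance records: the columns of
#'   [hco_parameters()], `label`, and optionally `period_s`,
#'   `spike_freq_hz`, `duty_pct`, `phase`, `cv_period`, `cv_amp`,
#'   `fail_flags`.
#' @param path Output file path.
#' @return `records`, invisibly.
#' @seealso [read_instance_db()]
#' @export
write_instance_db <- function(records, path) {
  check_point_columns(records, "records")
  if (!"label" %in% names(records)) abort("`records` needs a `label` column.")
  bad <- setdiff(unique(records$label), .hco_labels)
  if (length(bad)) abort(paste0("Unknown activity label(s): ", toString(bad)))
  out <- records
  for (col in c("period_s", "spike_freq_hz", "duty_pct", "phase",
                "cv_period", "cv_amp")) {
    if (!col %in% names(out)) out[[col]] <- NA_real_
  }
  if (!"fail_flags" %in% names(out)) out$fail_flags <- NA_character_
  out <- rename(out, e_leak_mV = "e_leak")[.db_cols]
  writeLines(.db_header, path)
  readr::write_tsv(out, path, na = "", col_names = TRUE, append = TRUE)
  invisible(records)
}

#' Read an instance table
#'
#' Reads a file written by [write_instance_db()], validating the version
#' header, the column set, numeric fields and activity labels.  Malformed
#' rows raise an error naming the (1-based) data row.
#'
#' @param path Path to a TSV instance table.
#' @return A tibble of instance records (with `e_leak` in mV).
#' @export
read_instance_db <- function(path) {
  first <- readLines(path, n = 1)
  if (!identical(first, .db_header)) {
    abort(paste0("Not an hcofam instance table (bad header): ", path))
  }
  raw <- readr::read_tsv(path, skip = 1, col_types = readr::cols(
    .default = readr::col_character()
  ), na = character(), progress = FALSE)
  missing <- setdiff(.db_cols, names(raw))
  if (length(missing)) {
    abort(paste0("Instance table missing column(s): ", toString(missing)))
  }
  num_cols <- setdiff(.db_cols, c("label", "fail_flags"))
  out <- raw
  for (col in num_cols) {
    vals <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(vals))
    bad <- which(is.na(parsed) & vals != "")
    if (length(bad)) {
      abort(paste0("Malformed numeric value in column `", col, "` at row ",
                   bad[1], ": \"", vals[bad[1]], "\""))
    }
    parsed[vals == ""] <- NA_real_
    out[[col]] <- parsed
  }
  bad_lab <- which(!raw$label %in% .hco_labels)
  if (length(bad_lab)) {
    abort(paste0("Unknown activity label at row ", bad_lab[1], ": \"",
                 raw$label[bad_lab[1]], "\""))
  }
  out$fail_flags[out$fail_flags == ""] <- NA_character_
  rename(out, e_leak = "e_leak_mV")
}
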