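# One-parameter families: construction, size tabulation, missing-member
# attribution and ensemble selection.

#' Build one-parameter families
#'
#' Groups a label-homogeneous set of instances (e.g. all realistic HCOs) by
#' [context_key()]: every group of instances that agree on all varied
#' parameters except the defining one becomes a family.  Singletons are
#' one-member families and count as noninterrupted by convention.  The
#' family sequence spans the permissible range from the smallest to the
#' largest member value; grid levels absent inside that range interrupt the
#' family, levels outside it are missing-outside members.
#'
#' @param group Tibble of instances (grid-point columns required; rows must
#'   lie on the grid).
#' @param defining Defining parameter (`"x_h"` or `"h"` style).
#' @param spec The [grid_spec()] the instances were drawn from.
#' @return A tibble of class `hco_families`, one row per family:
#'   `defining`, `context_key`, the seven context parameter columns,
#'   `n_members`, `begin`, `end`, `interrupted`, and list-columns
#'   `members`, `missing_inside`, `missing_outside`.
#' @examples
#' db <- make_synthetic_db(grid_spec(fractions = c(0.75, 1.25, 1.75),
#'                                   e_leak_levels = c(-60, -55)), seed = 1)
#' fams <- build_families(dplyr::filter(db, label == "rHCO"), "h",
#'                        grid_spec(fractions = c(0.75, 1.25, 1.75),
#'                                  e_leak_levels = c(-60, -55)))
#' @export
build_families <- function(group, defining, spec) {
  defining <- resolve_param(defining)
  check_point_columns(group, "group")
  levels <- spec[[defining]]
  off <- !group[[defining]] %in% levels
  for (p in setdiff(.hco_params, defining)) {
    off <- off | !group[[p]] %in% spec[[p]]
  }
  if (any(off)) {
    abort(paste0("Instance off-grid at row ", which(off)[1]))
  }
  if (anyDuplicated(paste(context_key(group, defining),
                          group[[defining]]))) {
    abort("Duplicate instances at the same grid point.")
  }
  others <- setdiff(.hco_params, defining)
  fams <- group |>
    mutate(.ck = context_key(group, defining)) |>
    group_by(.data$.ck) |>
    summarise(across(all_of(others), dplyr::first),
              members = list(sort(.data[[defining]])),
              .groups = "drop")
  fams <- fams |>
    mutate(defining = defining,
           n_members = map_int(.data$members, length),
           begin = map_dbl(.data$members, min),
           end = map_dbl(.data$members, max),
           missing_inside = map(.data$members, function(m) {
             setdiff(levels[levels > min(m) & levels < max(m)], m)
           }),
           missing_outside = map(.data$members, function(m) {
             levels[levels < min(m) | levels > max(m)]
           }),
           interrupted = map_int(.data$missing_inside, length) > 0) |>
    rename(context_key = ".ck") |>
    relocate("defining", "context_key", all_of(others), "n_members",
             "begin", "end", "interrupted")
  class(fams) <- c("hco_families", class(fams))
  fams
}

#' Tabulate family sizes
#'
#' Counts families per size (number of members), split into total and
#' noninterrupted, over all sizes the grid allows.
#'
#' @param families An [build_families()] result.
#' @param n_levels Number of grid levels of the defining parameter (maximum
#'   family size); defaults to the largest size present.
#' @return A tibble of class `hco_family_sizes`: `size`, `total`,
#'   `noninterrupted`.
#' @export
tabulate_sizes <- function(families, n_levels = NULL) {
  max_size <- if (!is.null(n_levels)) n_levels
  else if (nrow(families)) max(families$n_members) else 1L
  counts <- tibble(size = seq_len(max_size)) |>
    left_join(families |>
                group_by(size = .data$n_members) |>
                summarise(total = n(),
                          noninterrupted = sum(!.data$interrupted),
                          .groups = "drop"),
              by = "size") |>
    mutate(total = dplyr::coalesce(.data$total, 0L),
           noninterrupted = dplyr::coalesce(.data$noninterrupted, 0L))
  class(counts) <- c("hco_family_sizes", class(counts))
  counts
}

#' Attribute missing family members
#'
#' Looks up, in the full labeled database, the instance at every missing
#' grid point of every family (both interruptions inside the permissible
#' range and levels outside it) and records its activity label.  Missing
#' members with functional HCO bursting are additionally binned by the
#' physiological criteria they fail (from stored `fail_flags`, or recomputed
#' from characteristics when absent).
#'
#' @param families An [build_families()] result.
#' @param full_db Tibble with a `label` for every grid point (and ideally
#'   `fail_flags` or characteristics).
#' @return Tibble with one row per missing member: `defining`,
#'   `context_key`, `family_size`, `interrupted`, `fraction`, `where`
#'   (`"inside"`/`"outside"`), `label`, `category` (fHCO only).
#' @export
attribute_missing <- function(families, full_db) {
  if (nrow(families) == 0) {
    return(tibble(defining = character(), context_key = character(),
                  family_size = integer(), interrupted = logical(),
                  fraction = double(), where = character(),
                  label = character(), category = character()))
  }
  defining <- families$defining[1]
  others <- setdiff(.hco_params, defining)
  long <- families |>
    select("context_key", all_of(others), "n_members", "interrupted",
           "missing_inside", "missing_outside") |>
    tidyr::pivot_longer(c("missing_inside", "missing_outside"),
                        names_to = "where", values_to = "fraction") |>
    mutate(where = sub("missing_", "", .data$where)) |>
    tidyr::unnest("fraction")
  if (nrow(long) == 0) {
    return(tibble(defining = character(), context_key = character(),
                  family_size = integer(), interrupted = logical(),
                  fraction = double(), where = character(),
                  label = character(), category = character()))
  }
  long[[defining]] <- long$fraction
  lookup <- full_db |> select(all_of(.hco_params), "label",
                              dplyr::any_of(c("fail_flags", "period_s",
                                              "spike_freq_hz", "duty_pct")))
  joined <- left_join(long, lookup, by = .hco_params)
  if (anyNA(joined$label)) {
    miss <- joined[which(is.na(joined$label))[1], .hco_params]
    abort(paste0("Grid point absent from full_db: ",
                 paste(names(miss), unlist(miss), sep = "=",
                       collapse = ", ")))
  }
  category <- rep(NA_character_, nrow(joined))
  fh <- joined$label == "fHCO"
  if (any(fh)) {
    if ("fail_flags" %in% names(joined) && !anyNA(joined$fail_flags[fh])) {
      category[fh] <- mask_to_category(joined$fail_flags[fh])
    } else {
      category[fh] <- realistic_flags(joined$period_s[fh],
                                      joined$spike_freq_hz[fh],
                                      joined$duty_pct[fh])$category
    }
  }
  joined |>
    mutate(defining = defining, family_size = .data$n_members,
           category = category) |>
    select("defining", "context_key", "family_size", "interrupted",
           "fraction", "where", "label", "category")
}

#' Breakdown of missing members by label and failed criteria
#'
#' Per-family-size composition of missing members: counts (and fractions) of
#' each activity label, and for functional-HCO missing members the count per
#' failed-criteria category.
#'
#' @param attribution An [attribute_missing()] result.
#' @param scope Which missing members to include: `"all"`, `"inside"`
#'   (interruptions only) or `"outside"`.
#' @return A list of tibbles: `by_label` (`family_size`, `label`, `n`,
#'   `frac`) and `fhco_categories` (`family_size`, `category`, `n`).
#' @export
missing_breakdown <- function(attribution, scope = c("all", "inside",
                                                     "outside")) {
  scope <- match.arg(scope)
  if (scope != "all") attribution <- filter(attribution,
                                            .data$where == scope)
  by_label <- attribution |>
    count(.data$family_size, .data$label, name = "n") |>
    group_by(.data$family_size) |>
    mutate(frac = .data$n / sum(.data$n)) |>
    ungroup()
  fhco <- attribution |>
    filter(.data$label == "fHCO") |>
    count(.data$family_size, .data$category, name = "n")
  list(by_label = by_label, fhco_categories = fhco)
}

#' Select ensembles of model instances
#'
#' Keeps noninterrupted families with more than `min_members` members whose
#' context has nonzero fractions for every conductance (the defining
#' parameter aside).  Optionally requires that the synapse-free counterpart
#' of every member (`x_SynS = 0`, `x_SynG = 0`, all else equal) carries a
#' given isolated-neuron label, e.g. `"spiking"` or `"realistic_burster"`.
#'
#' @param families An [build_families()] result.
#' @param full_db Full labeled database (needed for `isolated_label`).
#' @param min_members Size threshold; families must have strictly more
#'   members (default 4).
#' @param isolated_label Optional activity label required of every member's
#'   synapse-free counterpart.
#' @return The selected subset of `families`.
#' @export
select_ensembles <- function(families, full_db = NULL, min_members = 4,
                             isolated_label = NULL) {
  if (min_members < 2) abort("`min_members` must be at least 2.")
  defining <- if (nrow(families)) families$defining[1] else "x_h"
  g_context <- setdiff(.hco_fractions, defining)
  sel <- filter(families, !.data$interrupted,
                .data$n_members > min_members)
  if (nrow(sel)) {
    nonzero <- purrr::reduce(map(g_context, function(p) sel[[p]] != 0), `&`)
    sel <- sel[nonzero, ]
  }
  if (!is.null(isolated_label)) {
    if (!isolated_label %in% .hco_labels) {
      abort(paste0("Unknown activity label: ", isolated_label))
    }
    if (is.null(full_db)) abort("`full_db` is required for isolated_label.")
    keep <- map_lgl(seq_len(nrow(sel)), function(i) {
      fam <- sel[i, ]
      pts <- tibble(!!defining := fam$members[[1]])
      for (p in setdiff(.hco_params, defining)) pts[[p]] <- fam[[p]]
      pts$x_SynS <- 0
      pts$x_SynG <- 0
      hit <- left_join(pts, select(full_db, all_of(.hco_params), "label"),
                       by = .hco_params)
      all(!is.na(hit$label) & hit$label == isolated_label)
    })
    sel <- sel[keep, ]
  }
  sel
}
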