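test_that("family construction matches the O(N^2) pairwise oracle", {
  spec <- tiny_spec()
  db <- make_synthetic_db(spec, seed = 17)
  group <- dplyr::filter(db, label == "fHCO")
  # stay within oracle budget
  expect_lte(nrow(group), 500)
  expect_gt(nrow(group), 10)
  for (p in c("x_h", "x_K2", "e_leak")) {
    fams <- build_families(group, p, spec)
    expect_equal(sort_sets(family_member_sets(fams)),
                 sort_sets(oracle_families(group, p)),
                 info = p)
  }
})

test_that("partition identity holds on every synthetic database", {
  spec <- toy_spec()
  db <- make_synthetic_db(spec, seed = 23)
  for (lab in c("rHCO", "fHCO", "asymmetric")) {
    group <- dplyr::filter(db, label == lab)
    if (nrow(group) == 0) next
    fams <- build_families(group, "h", spec)
    sizes <- tabulate_sizes(fams, n_levels = length(spec$x_h))
    expect_equal(sum(sizes$size * sizes$total), nrow(group), info = lab)
    expect_true(all(sizes$noninterrupted <= sizes$total))
  }
})

test_that("interruption status and permissible range are correct", {
  spec <- grid_spec(fractions = seq(0, 1.75, by = 0.25),
                    e_leak_levels = -60)
  base <- tibble::tibble(x_P = 1, x_K2 = 1, x_Leak = 1, x_CaS = 1,
                         x_SynS = 1, x_SynG = 1, e_leak = -60)
  # members at 0.5, 1.0, 1.5: levels 0.75 and 1.25 missing inside
  g1 <- dplyr::bind_rows(dplyr::mutate(base, x_h = 0.5),
                         dplyr::mutate(base, x_h = 1),
                         dplyr::mutate(base, x_h = 1.5))
  f1 <- build_families(g1, "h", spec)
  expect_equal(nrow(f1), 1)
  expect_true(f1$interrupted)
  expect_equal(f1$begin, 0.5)
  expect_equal(f1$end, 1.5)
  expect_equal(sort(f1$missing_inside[[1]]), c(0.75, 1.25))
  expect_equal(sort(f1$missing_outside[[1]]), c(0, 0.25, 1.75))
  # contiguous members are noninterrupted
  g2 <- dplyr::bind_rows(dplyr::mutate(base, x_h = 0.75),
                         dplyr::mutate(base, x_h = 1))
  f2 <- build_families(g2, "h", spec)
  expect_false(f2$interrupted)
  # singletons are noninterrupted by convention
  g3 <- dplyr::mutate(base, x_h = 1)
  f3 <- build_families(g3, "h", spec)
  expect_equal(f3$n_members, 1L)
  expect_false(f3$interrupted)
})

test_that("off-grid and duplicate instances are rejected", {
  spec <- tiny_spec()
  base <- tibble::tibble(x_P = 1, x_K2 = 1, x_Leak = 1, x_CaS = 1, x_h = 1,
                         x_SynS = 1, x_SynG = 1, e_leak = -60)
  expect_error(build_families(dplyr::mutate(base, x_h = 0.8), "h", spec),
               "off-grid")
  expect_error(build_families(dplyr::bind_rows(base, base), "h", spec),
               "Duplicate")
})

test_that("attribute_missing looks up labels and fHCO categories", {
  spec <- toy_spec()
  db <- make_synthetic_db(spec, seed = 23)
  group <- dplyr::filter(db, label == "rHCO")
  fams <- build_families(group, "h", spec)
  attribution <- attribute_missing(fams, db)
  n_missing <- sum(purrr::map_int(fams$missing_inside, length)) +
    sum(purrr::map_int(fams$missing_outside, length))
  expect_equal(nrow(attribution), n_missing)
  expect_true(all(attribution$label %in% hco_activity_labels()))
  fh <- attribution[attribution$label == "fHCO", ]
  expect_true(all(!is.na(fh$category)))
  expect_true(all(is.na(attribution$category[attribution$label != "fHCO"])))
  # interrupted families are exactly those with inside missing members
  inside_keys <- unique(attribution$context_key[attribution$where == "inside"])
  expect_setequal(inside_keys, fams$context_key[fams$interrupted])
})

test_that("attribute_missing errors when a grid point is not in the db", {
  spec <- tiny_spec()
  db <- make_synthetic_db(spec, seed = 17)
  group <- dplyr::filter(db, label == "rHCO")
  fams <- build_families(group, "h", spec)
  expect_gt(sum(purrr::map_int(fams$missing_outside, length) +
                  purrr::map_int(fams$missing_inside, length)), 0)
  expect_error(attribute_missing(fams, db[0, ]), "absent")
})

test_that("missing_breakdown splits by scope and normalizes fractions", {
  spec <- toy_spec()
  db <- make_synthetic_db(spec, seed = 23)
  fams <- build_families(dplyr::filter(db, label == "rHCO"), "h", spec)
  attribution <- attribute_missing(fams, db)
  bd <- missing_breakdown(attribution, scope = "all")
  sums <- bd$by_label |>
    dplyr::group_by(family_size) |>
    dplyr::summarise(s = sum(frac))
  expect_true(all(abs(sums$s - 1) < 1e-9))
  bd_in <- missing_breakdown(attribution, scope = "inside")
  expect_lte(sum(bd_in$by_label$n), sum(bd$by_label$n))
})

test_that("select_ensembles applies size, interruption and context filters", {
  spec <- toy_spec()
  db <- make_synthetic_db(spec, seed = 23)
  fams <- build_families(dplyr::filter(db, label == "rHCO"), "h", spec)
  sel <- select_ensembles(fams, min_members = 2)
  expect_true(all(!sel$interrupted))
  expect_true(all(sel$n_members > 2))
  for (p in setdiff(hco_parameters(fractions_only = TRUE), "x_h")) {
    expect_true(all(sel[[p]] != 0))
  }
  expect_error(select_ensembles(fams, min_members = 1), "at least 2")
  expect_error(select_ensembles(fams, db, min_members = 2,
                                isolated_label = "bogus"), "Unknown")
})
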