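test_that("burst_spec validates its arguments and requires a seed", {
  expect_error(burst_spec(), "seed")
  expect_error(burst_spec(period = -1, seed = 1), "period")
  expect_error(burst_spec(duty = 100, seed = 1), "duty")
  expect_error(burst_spec(phase = 1, seed = 1), "phase")
  expect_s3_class(burst_spec(seed = 1), "hco_burst_spec")
})

test_that("synthesized traces are deterministic given the seed", {
  spec <- burst_spec(noise_sd = 1, seed = 99, duration = 10)
  t1 <- synthesize_trace_pair(spec)
  t2 <- synthesize_trace_pair(spec)
  expect_identical(t1$v_a, t2$v_a)
  t3 <- synthesize_trace_pair(burst_spec(noise_sd = 1, seed = 100,
                                         duration = 10))
  expect_false(identical(t1$v_a, t3$v_a))
  # the generator does not disturb the global RNG stream
  set.seed(1); before <- stats::runif(1)
  set.seed(1); invisible(synthesize_trace_pair(spec)); after <- stats::runif(1)
  expect_identical(before, after)
})

test_that("ground-truth spike attributes match detected spikes", {
  spec <- burst_spec(period = 6, duty = 50, spike_freq = 10, seed = 3,
                     duration = 30)
  tr <- synthesize_trace_pair(spec)
  truth <- attr(tr, "spikes_a")
  found <- detect_spikes(tr$time, tr$v_a)
  expect_equal(nrow(found), length(truth))
  expect_equal(found$time, truth, tolerance = 2 * spec$dt)
})

test_that("bursts too short for three spikes are rejected", {
  expect_error(
    synthesize_trace_pair(burst_spec(period = 2, duty = 5, spike_freq = 10,
                                     seed = 1)),
    "three spikes")
  # spike_freq = 0 gives spikeless plateaus without error
  tr <- synthesize_trace_pair(burst_spec(spike_freq = 0, seed = 1,
                                         duration = 30))
  expect_equal(nrow(detect_spikes(tr$time, tr$v_a)), 0)
})

test_that("grid_response honors the rule precedence", {
  base <- tibble::tibble(x_P = 1, x_K2 = 1, x_Leak = 1, x_CaS = 1, x_h = 1,
                         x_SynS = 1, x_SynG = 1, e_leak = -60)
  pts <- dplyr::bind_rows(
    base,                                        # canonical -> rHCO
    dplyr::mutate(base, x_P = 0),                # silent beats everything
    dplyr::mutate(base, x_SynS = 0, x_SynG = 0), # synapse-free burster
    dplyr::mutate(base, x_SynS = 0, x_SynG = 0, x_CaS = 0.25),  # spiking
    dplyr::mutate(base, x_K2 = 0),               # plateau
    dplyr::mutate(base, x_SynS = 0.25, x_SynG = 0.25),  # weak synapses
    dplyr::mutate(base, x_CaS = 0.5)             # asymmetric
  )
  res <- grid_response(pts)
  expect_equal(res$label,
               c("rHCO", "silent", "realistic_burster", "spiking", "plateau",
                 "spiking", "asymmetric"))
})

test_that("canonical point yields the nominal characteristics", {
  canonical <- tibble::tibble(x_P = 1, x_K2 = 1, x_Leak = 1, x_CaS = 1,
                              x_h = 1, x_SynS = 1, x_SynG = 1, e_leak = -60)
  res <- grid_response(canonical)
  expect_equal(res$label, "rHCO")
  expect_equal(res$period_s, 10)
  expect_equal(res$spike_freq_hz, 15)
  expect_equal(res$duty_pct, 60)
  expect_equal(res$phase, 0.5)
  expect_equal(res$fail_flags, "---")
})

test_that("period responds monotonically to x_h along a family line", {
  pts <- tibble::tibble(x_P = 1, x_K2 = 1, x_Leak = 1, x_CaS = 1,
                        x_h = seq(0.25, 1.75, by = 0.25), x_SynS = 1,
                        x_SynG = 1, e_leak = -60)
  res <- grid_response(pts)
  expect_true(all(diff(res$period_s) < 0))
})

test_that("make_synthetic_db requires a seed and is reproducible", {
  spec <- tiny_spec()
  expect_error(make_synthetic_db(spec), "seed")
  d1 <- make_synthetic_db(spec, seed = 5)
  d2 <- make_synthetic_db(spec, seed = 5)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), grid_size(spec))
  noisy <- make_synthetic_db(spec, response_model(noise_sd = 0.05), seed = 5)
  expect_false(identical(noisy$period_s, d1$period_s))
  # jitter re-applies the realistic/functional split consistently
  rh <- noisy[noisy$label == "rHCO", ]
  expect_true(all(rh$period_s >= 5 & rh$period_s <= 15))
  expect_true(all(rh$fail_flags == "---"))
})

test_that("fixture tables load with verified checksums", {
  fx <- load_fixture_tables()
  expect_named(fx, c("table1", "table2", "table3"))
  expect_true(all(c("param", "size", "total", "noninterrupted") %in%
                    names(fx$table1)))
  expect_true(all(fx$table1$noninterrupted <= fx$table1$total))
  expect_true(all(fx$table1$total >= 0))
})
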