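# Helper: write a minimal model config to a temp file and load it.
local_model <- function(yaml_list, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".yaml", .local_envir = env)
  yaml::write_yaml(yaml_list, path)
  read_model_config(path)
}

leak_only <- function(g = 8, e = -60, C = 0.5) {
  list(name = "leak_only", capacitance_nF = C,
       currents = list(list(name = "leak", g_nS = g, E_mV = e)),
       synapses = list(),
       scaling = list(x_Leak = "leak"))
}

test_that("config validation rejects malformed models", {
  bad_cap <- leak_only(); bad_cap$capacitance_nF <- NULL
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(bad_cap, path)
  expect_error(read_model_config(path), "capacitance")
  bad_syn <- leak_only()
  bad_syn$synapses <- list(list(name = "S", kind = "electrical", g_nS = 1,
                                E_mV = -60, act = list(vhalf = -40, k = 2)))
  yaml::write_yaml(bad_syn, path)
  expect_error(read_model_config(path), "synapse kind")
  bad_tau <- leak_only()
  bad_tau$currents[[1]]$gates <- list(list(power = 1,
                                           inf = list(vhalf = -40, k = 4),
                                           tau = list(type = "const",
                                                      value = -1)))
  yaml::write_yaml(bad_tau, path)
  expect_error(read_model_config(path), "positive")
})

test_that("the packaged surrogate config loads and is well formed", {
  model <- surrogate_config()
  expect_s3_class(model, "hco_model_config")
  expect_gt(model$C, 0)
  names_cur <- vapply(model$currents, function(cu) cu$name, character(1))
  expect_true(all(c("Na", "K1", "P", "CaS", "K2", "h", "leak") %in%
                    names_cur))
  names_syn <- vapply(model$synapses, function(sy) sy$name, character(1))
  expect_setequal(names_syn, c("SynS", "SynG"))
  layout <- hcofam:::state_layout(model)
  expect_equal(length(layout$names), 2 * layout$n_cell + 4)
})

test_that("default states put gates at steady state", {
  model <- surrogate_config()
  s <- hcofam:::default_states(model, v_a = -40, v_b = -60)
  expect_equal(unname(s["V_A"]), -40)
  expect_equal(unname(s["V_B"]), -60)
  # every dynamic gate equals its inf at the cell's voltage
  for (cu in model$currents) {
    for (j in seq_along(cu$gates)) {
      g <- cu$gates[[j]]
      if (!is.null(g$tau)) {
        nm <- paste0(cu$name, "_g", j)
        expect_equal(unname(s[paste0(nm, "_A")]), g$inf(-40), info = nm)
        expect_equal(unname(s[paste0(nm, "_B")]), g$inf(-60), info = nm)
      }
    }
  }
  expect_true(all(s[grepl("^Syn", names(s))] == 0))
})

test_that("leak-only relaxation matches the closed-form exponential", {
  model <- local_model(leak_only(g = 8, e = -60, C = 0.5))
  proto <- sim_protocol(t_init = 0, t_settle = 0, t_record = 0.5,
                        dt = 0.001, tol = 1e-8)
  tr <- simulate_pair(tibble::tibble(x_Leak = 1, e_leak = -60), model, proto,
                      state0 = hcofam:::default_states(model, v_a = -40,
                                                       v_b = -60))
  tau <- 0.5 / 8                      # C / g  (nF / nS = s)
  analytic <- -60 + 20 * exp(-tr$time / tau)
  excursion <- 20
  expect_lt(max(abs(tr$v_a - analytic)) / excursion, 1e-3)
  expect_lt(max(abs(tr$v_b - (-60))), 1e-9)
})

test_that("zero-conductance scaling freezes the membrane potential", {
  model <- local_model(leak_only())
  proto <- sim_protocol(t_init = 0, t_settle = 0, t_record = 0.2)
  tr <- simulate_pair(tibble::tibble(x_Leak = 0), model, proto,
                      state0 = hcofam:::default_states(model, v_a = -40,
                                                       v_b = -55))
  expect_true(all(abs(tr$v_a - (-40)) < 1e-9))
  expect_true(all(abs(tr$v_b - (-55)) < 1e-9))
})

test_that("the e_leak override moves the leak reversal", {
  model <- local_model(leak_only(g = 8, e = -60, C = 0.5))
  proto <- sim_protocol(t_init = 0, t_settle = 0, t_record = 1, tol = 1e-8)
  tr <- simulate_pair(tibble::tibble(x_Leak = 1, e_leak = -50), model, proto,
                      state0 = hcofam:::default_states(model, v_a = -40,
                                                       v_b = -60))
  expect_equal(tr$v_a[length(tr$v_a)], -50, tolerance = 1e-5)
  expect_equal(tr$v_b[length(tr$v_b)], -50, tolerance = 1e-5)
})

test_that("identical cell states evolve identically (symmetry)", {
  model <- surrogate_config()
  proto <- sim_protocol(t_init = 0, t_settle = 0, t_record = 1)
  s0 <- hcofam:::default_states(model, v_a = -50, v_b = -50)
  tr <- simulate_pair(tibble::tibble(x_h = 1), model, proto, state0 = s0)
  expect_equal(tr$v_a, tr$v_b, tolerance = 1e-10)
})

test_that("with synapses off the cells are independent", {
  model <- surrogate_config()
  point <- tibble::tibble(x_SynS = 0, x_SynG = 0)
  # exact check at the vector-field level: cell A's derivatives do not
  # depend on cell B's state when both synapses are scaled to zero
  scale <- hcofam:::scale_from_point(model, point)
  rhs <- hcofam:::make_rhs(model, scale)
  nc <- hcofam:::state_layout(model)$n_cell
  s1 <- hcofam:::default_states(model, -40, -60)
  s2 <- hcofam:::default_states(model, -40, -80)
  d1 <- rhs(0, s1, NULL)[[1]]
  d2 <- rhs(0, s2, NULL)[[1]]
  expect_identical(d1[seq_len(nc)], d2[seq_len(nc)])
  expect_false(isTRUE(all.equal(d1[nc + 1], d2[nc + 1])))
  # and over an integrated window, A's spike times agree to solver accuracy
  proto <- sim_protocol(t_init = 0, t_settle = 0, t_record = 1)
  tr1 <- simulate_pair(point, model, proto, state0 = s1)
  tr2 <- simulate_pair(point, model, proto, state0 = s2)
  sp1 <- attr(tr1, "spikes_a"); sp2 <- attr(tr2, "spikes_a")
  expect_equal(length(sp1), length(sp2))
  expect_lt(max(abs(sp1 - sp2)), 2e-3)
  expect_gt(max(abs(tr1$v_b - tr2$v_b)), 1)
})

test_that("the shared initial state is deterministic and asymmetric", {
  model <- surrogate_config()
  proto <- sim_protocol(t_init = 5)
  s1 <- make_initial_state(model, proto)
  s2 <- make_initial_state(model, proto)
  expect_identical(s1, s2)
  expect_false(isTRUE(all.equal(unname(s1["V_A"]), unname(s1["V_B"]))))
  # t_init = 0 returns the documented defaults
  s0 <- make_initial_state(model, sim_protocol(t_init = 0))
  expect_equal(unname(s0["V_A"]), -40)
  expect_equal(unname(s0["V_B"]), -60)
})

test_that("solutions converge as the tolerance tightens", {
  # smooth non-spiking relaxation: leak plus one slow gate
  cfg <- leak_only(g = 8, e = -60, C = 0.5)
  cfg$currents <- c(cfg$currents, list(list(
    name = "K2", g_nS = 10, E_mV = -70,
    gates = list(list(power = 1, inf = list(vhalf = -45, k = 4),
                      tau = list(type = "const", value = 0.5))))))
  model <- local_model(cfg)
  s0 <- hcofam:::default_states(model, v_a = -40, v_b = -60)
  run <- function(tol) {
    proto <- sim_protocol(t_init = 0, t_settle = 0, t_record = 2, tol = tol)
    simulate_pair(tibble::tibble(x_Leak = 1), model, proto, state0 = s0)
  }
  coarse <- run(1e-5)
  fine <- run(1e-9)
  expect_lt(max(abs(coarse$v_a - fine$v_a)), 1e-3)
})

test_that("trace pairs round-trip through TSV", {
  tr <- synthesize_trace_pair(burst_spec(seed = 8, duration = 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace_pair(tr, path)
  back <- read_trace_pair(path)
  expect_equal(back$v_a, tr$v_a, tolerance = 1e-9)
  expect_s3_class(back, "hco_trace_pair")
})
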