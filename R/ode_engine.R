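# Config-driven two-cell conductance-based simulator.  Current kinetics are
# supplied by a structured config file (parametric sigmoid/Gaussian gate
# functions), not hard-coded; the packaged surrogate config is the test
# vehicle.  Both cells always share the same parameter values; they differ
# only in their initial states.

#' Simulation protocol
#'
#' Timing and solver settings of the simulation contract: the canonical
#' model is integrated for `t_init` seconds to obtain the shared initial
#' state (one cell bursting, the other inhibited); each instance is then run
#' for `t_settle` seconds to establish stable activity and a further
#' `t_record` seconds that are recorded.  `dt` is the dense-output interval
#' of the recorded trace; integration itself uses a stiff-capable
#' variable-step method (`deSolve::lsoda`) with relative tolerance `tol`.
#'
#' @param t_init Canonical initialization time (s), default 200.
#' @param t_settle Settling time (s), default 100.
#' @param t_record Recorded window (s), default 100.
#' @param dt Output sample interval (s), default 1 ms.
#' @param tol Solver relative tolerance.
#' @return An object of class `hco_sim_protocol`.
#' @export
sim_protocol <- function(t_init = 200, t_settle = 100, t_record = 100,
                         dt = 0.001, tol = 1e-6) {
  if (any(c(t_init, t_settle, t_record) < 0)) {
    abort("Durations must be non-negative.")
  }
  if (dt <= 0) abort("`dt` must be positive.")
  structure(list(t_init = t_init, t_settle = t_settle, t_record = t_record,
                 dt = dt, tol = tol), class = "hco_sim_protocol")
}

sigmoid_fun <- function(p) {
  vhalf <- p$vhalf; k <- p$k
  function(v) 1 / (1 + exp(-(v - vhalf) / k))
}

tau_fun <- function(p) {
  if (is.null(p) || identical(p$type, "instant")) return(NULL)
  switch(p$type,
         const = {
           val <- p$value
           if (val <= 0) abort("Time constants must be positive.")
           function(v) rep(val, length(v))
         },
         sigmoid = {
           base <- p$base; amp <- p$amp; vhalf <- p$vhalf; k <- p$k
           f <- function(v) base + amp / (1 + exp(-(v - vhalf) / k))
           probe <- f(seq(-120, 60, by = 1))
           if (any(probe <= 0)) abort("Time constants must be positive.")
           f
         },
         gauss = {
           base <- p$base; amp <- p$amp; vhalf <- p$vhalf; width <- p$width
           f <- function(v) base + amp * exp(-((v - vhalf) / width)^2)
           probe <- f(seq(-120, 60, by = 1))
           if (any(probe <= 0)) abort("Time constants must be positive.")
           f
         },
         abort(paste0("Unknown tau type: ", p$type)))
}

compile_config <- function(config) {
  currents <- map(config$currents, function(cu) {
    gates <- map(cu$gates %||% list(), function(g) {
      list(power = g$power %||% 1,
           inf = sigmoid_fun(g$inf),
           tau = tau_fun(g$tau))
    })
    list(name = cu$name, g = cu$g_nS, E = cu$E_mV, gates = gates)
  })
  synapses <- map(config$synapses %||% list(), function(sy) {
    if (!sy$kind %in% c("graded", "spike_mediated")) {
      abort(paste0("Unknown synapse kind: ", sy$kind))
    }
    list(name = sy$name, kind = sy$kind, g = sy$g_nS, E = sy$E_mV,
         act = sigmoid_fun(sy$act),
         tau = if (sy$kind == "graded") sy$tau else NULL,
         tau_rise = sy$tau_rise %||% NULL,
         tau_decay = sy$tau_decay %||% NULL)
  })
  list(name = config$name %||% "model",
       C = config$capacitance_nF,
       currents = currents, synapses = synapses,
       scaling = config$scaling %||% list(),
       raw = config)
}

#' Read a two-cell model configuration
#'
#' Parses the YAML model description: membrane capacitance, a list of
#' currents (maximal conductance, reversal potential, and gates given as
#' parametric sigmoid steady states with constant, sigmoid or Gaussian
#' voltage-dependent time constants), the two synapse kinds (graded and
#' spike-mediated), and the mapping from grid parameters to current names.
#'
#' @param path Path to a YAML model config.
#' @return An object of class `hco_model_config`.
#' @seealso [surrogate_config()] for the packaged surrogate model.
#' @export
read_model_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$capacitance_nF) || raw$capacitance_nF <= 0) {
    abort("Config needs a positive capacitance_nF.")
  }
  model <- compile_config(raw)
  structure(model, class = "hco_model_config")
}

#' The packaged surrogate model configuration
#'
#' A small two-cell model assembled for exercising the simulation contract:
#' an HH-type spiking pair (fast Na, delayed-rectifier K), a persistent Na
#' current, a slowly inactivating low-threshold Ca current, a slow
#' persistent K current, an h-like hyperpolarization-activated current, leak,
#' and both graded and spike-mediated inhibitory synapses.  Its parameters
#' are original to this package and stated in full in the config file.
#'
#' @return An `hco_model_config`.
#' @export
surrogate_config <- function() {
  read_model_config(system.file("extdata", "surrogate_model.yaml",
                                package = "hcofam", mustWork = TRUE))
}

# State layout: for each cell, V followed by its dynamic gates (in current
# order); then one drive state per synapse per direction (A->B, B->A).
state_layout <- function(model) {
  gate_names <- unlist(map(model$currents, function(cu) {
    dyn <- which(map_lgl(cu$gates, function(g) !is.null(g$tau)))
    if (length(dyn)) paste0(cu$name, "_g", dyn) else character(0)
  }))
  per_cell <- c("V", gate_names)
  syn <- unlist(map(model$synapses, function(sy) {
    paste0(sy$name, c("_ab", "_ba"))
  }))
  list(per_cell = per_cell,
       n_cell = length(per_cell),
       names = c(paste0(per_cell, "_A"), paste0(per_cell, "_B"), syn))
}

default_states <- function(model, v_a = -40, v_b = -60) {
  layout <- state_layout(model)
  fill_cell <- function(v0) {
    s <- v0
    for (cu in model$currents) {
      for (g in cu$gates) {
        if (!is.null(g$tau)) s <- c(s, g$inf(v0))
      }
    }
    s
  }
  syn0 <- rep(0, 2 * length(model$synapses))
  stats::setNames(c(fill_cell(v_a), fill_cell(v_b), syn0), layout$names)
}

# Ionic + synaptic RHS.  `scale` holds per-current multiplicative factors and
# an e_leak override, applied at call time so one compiled model serves the
# whole grid.
make_rhs <- function(model, scale = NULL) {
  layout <- state_layout(model)
  nc <- layout$n_cell
  n_syn <- length(model$synapses)
  cfac <- map_dbl(model$currents, function(cu) {
    (scale$currents[[cu$name]] %||% 1)
  })
  sfac <- map_dbl(model$synapses %||% list(), function(sy) {
    (scale$synapses[[sy$name]] %||% 1)
  })
  e_leak <- scale$e_leak %||% NULL
  C <- model$C

  cell_current <- function(v, gates_state) {
    i_total <- 0
    gi <- 0
    for (j in seq_along(model$currents)) {
      cu <- model$currents[[j]]
      open <- 1
      for (g in cu$gates) {
        if (is.null(g$tau)) {
          x <- g$inf(v)
        } else {
          gi <- gi + 1
          x <- gates_state[gi]
        }
        open <- open * x^g$power
      }
      E <- if (!is.null(e_leak) && cu$name == "leak") e_leak else cu$E
      i_total <- i_total + cfac[j] * cu$g * open * (v - E)
    }
    i_total
  }

  gate_derivs <- function(v, gates_state) {
    out <- numeric(length(gates_state))
    gi <- 0
    for (cu in model$currents) {
      for (g in cu$gates) {
        if (!is.null(g$tau)) {
          gi <- gi + 1
          out[gi] <- (g$inf(v) - gates_state[gi]) / g$tau(v)
        }
      }
    }
    out
  }

  function(t, state, parms) {
    va <- state[1]
    ga <- if (nc > 1) state[2:nc] else numeric(0)
    vb <- state[nc + 1]
    gb <- if (nc > 1) state[(nc + 2):(2 * nc)] else numeric(0)
    syn <- if (n_syn) state[(2 * nc + 1):(2 * nc + 2 * n_syn)] else numeric(0)

    isyn_a <- 0; isyn_b <- 0
    dsyn <- numeric(2 * n_syn)
    if (n_syn) {
      for (j in seq_len(n_syn)) {
        sy <- model$synapses[[j]]
        s_ab <- syn[2 * j - 1]   # drive from A onto B
        s_ba <- syn[2 * j]       # drive from B onto A
        isyn_b <- isyn_b + sfac[j] * sy$g * s_ab * (vb - sy$E)
        isyn_a <- isyn_a + sfac[j] * sy$g * s_ba * (va - sy$E)
        if (sy$kind == "graded") {
          dsyn[2 * j - 1] <- (sy$act(va) - s_ab) / sy$tau
          dsyn[2 * j] <- (sy$act(vb) - s_ba) / sy$tau
        } else {
          dsyn[2 * j - 1] <- sy$act(va) * (1 - s_ab) / sy$tau_rise -
            s_ab / sy$tau_decay
          dsyn[2 * j] <- sy$act(vb) * (1 - s_ba) / sy$tau_rise -
            s_ba / sy$tau_decay
        }
      }
    }
    dva <- -(cell_current(va, ga) + isyn_a) / C
    dvb <- -(cell_current(vb, gb) + isyn_b) / C
    list(c(dva, gate_derivs(va, ga), dvb, gate_derivs(vb, gb), dsyn))
  }
}

integrate_model <- function(model, state, t_end, dt, tol, scale = NULL,
                            times = NULL) {
  rhs <- make_rhs(model, scale)
  if (is.null(times)) times <- seq(0, t_end, by = dt)
  sol <- deSolve::lsoda(y = state, times = times, func = rhs, parms = NULL,
                        rtol = tol, atol = tol * 100, maxsteps = 50000)
  if (nrow(sol) < length(times) || any(!is.finite(sol))) {
    abort("Integration failed (non-finite state or solver abort).")
  }
  sol
}

.init_cache <- new.env(parent = emptyenv())

#' Initial state of the paired cells
#'
#' The shared initial state used for every grid point: the canonical
#' (unscaled) model is integrated for `t_init` seconds from the documented
#' default states (cell A depolarized at -40 mV, cell B at -60 mV, gates at
#' their steady-state values, synaptic drives at zero), so that one cell is
#' in its active phase and the other is inhibited.  The result is
#' deterministic, cached per (config, t_init, tolerance) and reused.
#'
#' @param model An [read_model_config()] result.
#' @param protocol A [sim_protocol()]; `t_init = 0` returns the default
#'   states unchanged.
#' @return Named numeric state vector.
#' @export
make_initial_state <- function(model, protocol = sim_protocol()) {
  stopifnot(inherits(model, "hco_model_config"))
  state <- default_states(model)
  if (protocol$t_init == 0) return(state)
  key <- rlang::hash(list(model$raw, protocol$t_init, protocol$tol))
  if (!is.null(.init_cache[[key]])) return(.init_cache[[key]])
  sol <- integrate_model(model, state, protocol$t_init,
                         dt = protocol$t_init / 2, tol = protocol$tol,
                         times = seq(0, protocol$t_init,
                                     length.out = max(2, ceiling(protocol$t_init / 0.5) + 1)))
  out <- sol[nrow(sol), -1]
  .init_cache[[key]] <- out
  out
}

scale_from_point <- function(model, point) {
  scaling <- model$scaling
  cur <- list(); syn <- list()
  syn_names <- map_chr(model$synapses %||% list(), "name")
  for (p in names(scaling)) {
    if (p == "e_leak" || !p %in% names(point)) next
    frac <- point[[p]]
    if (p != "e_leak" && frac < 0) abort("Conductance fractions must be >= 0.")
    target <- scaling[[p]]
    if (target %in% syn_names) syn[[target]] <- frac else cur[[target]] <- frac
  }
  list(currents = cur, synapses = syn,
       e_leak = if ("e_leak" %in% names(point)) point$e_leak else NULL)
}

#' Simulate one grid point
#'
#' Scales the configured maximal conductances by the point's fractions (both
#' cells always receive identical parameters), integrates the coupled pair
#' from the shared initial state for `t_settle + t_record` seconds, and
#' returns the final `t_record` window with the time base re-zeroed, plus
#' spike times extracted at the -20 mV threshold.
#'
#' @param point One-row tibble of grid parameters (any subset of
#'   [hco_parameters()]; absent parameters stay canonical).
#' @param model An [read_model_config()] result.
#' @param protocol A [sim_protocol()].
#' @param state0 Optional explicit initial state (defaults to
#'   [make_initial_state()]).
#' @return An `hco_trace_pair` tibble (`time`, `v_a`, `v_b`) with spike-time
#'   attributes `spikes_a`, `spikes_b`.
#' @examples
#' \donttest{
#' model <- surrogate_config()
#' proto <- sim_protocol(t_init = 5, t_settle = 0, t_record = 5)
#' tr <- simulate_pair(tibble::tibble(x_h = 1), model, proto)
#' }
#' @export
simulate_pair <- function(point, model, protocol = sim_protocol(),
                          state0 = NULL) {
  stopifnot(inherits(model, "hco_model_config"))
  scale <- scale_from_point(model, point)
  if (is.null(state0)) state0 <- make_initial_state(model, protocol)
  t_total <- protocol$t_settle + protocol$t_record
  times <- seq(0, t_total, by = protocol$dt)
  sol <- integrate_model(model, state0, t_total, protocol$dt, protocol$tol,
                         scale = scale, times = times)
  layout <- state_layout(model)
  keep <- sol[, "time"] >= protocol$t_settle - 1e-12
  tt <- sol[keep, "time"] - protocol$t_settle
  out <- tibble(time = tt,
                v_a = unname(sol[keep, 2]),
                v_b = unname(sol[keep, layout$n_cell + 2]))
  attr(out, "spikes_a") <- detect_spikes(out$time, out$v_a)$time
  attr(out, "spikes_b") <- detect_spikes(out$time, out$v_b)$time
  class(out) <- c("hco_trace_pair", class(out))
  out
}

#' Write / read a recorded trace pair as delimited text
#'
#' Two-column-per-cell TSV (`time`, `v_a`, `v_b`).
#' @param pair A trace-pair tibble.
#' @param path File path.
#' @return The tibble (read) or `pair` invisibly (write).
#' @export
write_trace_pair <- function(pair, path) {
  readr::write_tsv(as_tibble(pair), path)
  invisible(pair)
}

#' @rdname write_trace_pair
#' @export
read_trace_pair <- function(path) {
  out <- readr::read_tsv(path, col_types = "ddd", progress = FALSE)
  class(out) <- c("hco_trace_pair", class(out))
  out
}
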