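# Surrogate two-cell model for the simulation contract.
#
# All kinetics are parametric: gate steady states are sigmoids
# inf(V) = 1 / (1 + exp(-(V - vhalf) / k))  (k > 0 activates with
# depolarization, k < 0 with hyperpolarization); time constants are
# constant, sigmoid or Gaussian functions of voltage, in seconds.
# Conductances in nS, potentials in mV, capacitance in nF.
#
# The canonical maximal conductances match the grid's canonical set so that
# scale fractions apply directly.  These kinetics are original to this
# package (a synthetic stand-in, not a published cell model).
name: surrogate-hco
capacitance_nF: 0.5
spike_threshold_mV: -20
scaling:
  x_P: P
  x_K2: K2
  x_Leak: leak
  x_CaS: CaS
  x_h: h
  x_SynS: SynS
  x_SynG: SynG
currents:
  - name: Na            # fast spike generator; activation instantaneous
    g_nS: 200
    E_mV: 45
    gates:
      - power: 3
        inf: {vhalf: -34, k: 3}
        tau: {type: instant}
      - power: 1
        inf: {vhalf: -40, k: -4}
        tau: {type: const, value: 0.008}
  - name: K1            # delayed rectifier
    g_nS: 100
    E_mV: -70
    gates:
      - power: 2
        inf: {vhalf: -30, k: 4}
        tau: {type: const, value: 0.01}
  - name: P             # persistent Na
    g_nS: 7
    E_mV: 45
    gates:
      - power: 1
        inf: {vhalf: -50, k: 4}
        tau: {type: const, value: 0.02}
  - name: CaS           # slowly inactivating low-threshold Ca
    g_nS: 3.2
    E_mV: 135
    gates:
      - power: 1
        inf: {vhalf: -46, k: 4}
        tau: {type: const, value: 0.03}
      - power: 1
        inf: {vhalf: -52, k: -5}
        tau: {type: const, value: 2.5}
  - name: K2            # slow persistent K (burst termination): builds up
    g_nS: 80            # slowly during the depolarized burst and unloads
    E_mV: -70           # quickly at hyperpolarized potentials
    gates:
      - power: 1
        inf: {vhalf: -35, k: 4}
        tau: {type: sigmoid, base: 0.1, amp: 8, vhalf: -45, k: 4}
  - name: h             # hyperpolarization-activated cation (escape)
    g_nS: 4
    E_mV: -21
    gates:
      - power: 1
        inf: {vhalf: -58, k: -5}
        tau: {type: const, value: 0.8}
  - name: leak
    g_nS: 8
    E_mV: -60
synapses:
  - name: SynS          # spike-mediated inhibition
    kind: spike_mediated
    g_nS: 60
    E_mV: -62.5
    act: {vhalf: -20, k: 2}
    tau_rise: 0.004
    tau_decay: 0.12
  - name: SynG          # graded inhibition
    kind: graded
    g_nS: 30
    E_mV: -62.5
    act: {vhalf: -45, k: 3}
    tau: 0.08
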