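# Four-layer, two cell-type cortical column parameterization.
#
# Numeric constants transcribed from Potjans TC & Diesmann M (2014),
# "The cell-type specific cortical microcircuit: relating structure and
# activity in a full-scale spiking network model", Cerebral Cortex
# 24(3):785-806, Tables 4 and 5, with two modifications used by this
# package's shot-noise population-density model:
#   * the L4e -> L2/3e connection probability is doubled from 0.044 to
#     0.088 so that a single synaptic strength can be used for every
#     excitatory connection (the original model doubles the weight of
#     that one projection instead);
#   * the background Poisson rate is divided by `rescale` and the
#     background synaptic weight multiplied by the same factor, leaving
#     the mean background input unchanged while increasing its variance.
# Refractory periods are set to zero (negligible at these rates).

populations: [L23e, L23i, L4e, L4i, L5e, L5i, L6e, L6i]

# Table 1 / "Populations and inputs": full-scale neuron counts.
population_sizes: [20683, 5834, 21915, 5479, 4850, 1065, 14395, 2948]

# Connection probabilities, target (rows) x source (columns), ordered as
# `populations`. P&D Table 5 "Connectivity", with the 0.088 override in
# row L23e, column L4e.
conn_prob:
  L23e: [0.101, 0.169, 0.088, 0.082, 0.032, 0.0,    0.008, 0.0]
  L23i: [0.135, 0.137, 0.032, 0.052, 0.075, 0.0,    0.004, 0.0]
  L4e:  [0.008, 0.006, 0.050, 0.135, 0.007, 0.0003, 0.045, 0.0]
  L4i:  [0.069, 0.003, 0.079, 0.160, 0.003, 0.0,    0.106, 0.0]
  L5e:  [0.100, 0.062, 0.051, 0.006, 0.083, 0.373,  0.020, 0.0]
  L5i:  [0.055, 0.027, 0.026, 0.002, 0.060, 0.316,  0.009, 0.0]
  L6e:  [0.016, 0.007, 0.021, 0.017, 0.057, 0.020,  0.040, 0.225]
  L6i:  [0.036, 0.001, 0.003, 0.001, 0.028, 0.008,  0.066, 0.144]

# P&D Table 4 "Neuron model": integrate-and-fire parameters, voltages
# expressed relative to rest (threshold -50 mV, rest/reset -65 mV).
neuron:
  tau_m: 10.0        # membrane time constant, ms
  v_theta: 15.0      # spike threshold above rest, mV
  v_reset: 0.0       # reset potential (= rest), mV
  t_ref: 0.0         # refractory period simplified to zero, ms

# P&D Table 4/5 "Synapses": exponential postsynaptic currents.
synapse:
  current_amplitude: 87.8   # PSC amplitude w, pA
  tau_s: 0.5                # synaptic time constant, ms
  capacitance: 250.0        # membrane capacitance C_m, pF
  g_inh_ratio: 4.0          # |inhibitory| / excitatory weight ratio

# P&D Table 5 "Input": external background drive, one independent 8 Hz
# Poisson source per synapse; in-degrees per target population.
background:
  in_degree: [1600, 1500, 2100, 1900, 2000, 1900, 2900, 2100]
  rate: 8.0          # Hz per source
  rescale: 8.54      # rate / rescale, weight * rescale

# P&D Table 5 "Delays": conduction delays by source cell type, drawn
# per synapse from a normal distribution truncated at the simulation
# resolution; mean and sd in ms.
delays:
  excitatory: 1.5
  excitatory_sd: 0.75
  inhibitory: 0.75
  inhibitory_sd: 0.375
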