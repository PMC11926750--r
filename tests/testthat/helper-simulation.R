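# Constant-commitment simulation helper: fixes k3/k2 and back-computes
# pc0 from the requested commitment, with the duration set to reach f_end
# under the zero-order rate law.
sim_const_commitment <- function(c_target, kie3 = 1.028, kie1 = 1, kie2 = 1,
                                 delta0 = 23.6, f_end = 0.13, n_steps = 40L,
                                 rffd = 5e-7, o2_0 = 2.7e-4,
                                 k3_over_k2 = 253) {
  rate <- rffd * c_target / (1 + c_target)
  cond <- experiment_conditions("His", pc0 = c_target / k3_over_k2,
                                o2_0 = o2_0,
                                duration = (1 - f_end) * o2_0 / rate)
  par <- kinetic_params(k3 = k3_over_k2 * K2_SINGLET_O2,
                        rf = rffd / 0.75, f_delta = 0.75)
  simulate_experiment(cond, par, isotope_effects(kie3, kie1, kie2),
                      delta0 = delta0, n_steps = n_steps,
                      f_floor = f_end * 0.7)
}
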