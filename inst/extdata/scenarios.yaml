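# Named protection-assay scenarios. Densities are per ml, times in minutes.
# `c` is the CRISPR interference probability of the spacer-carrying strain
# in that medium (the knock-out control always runs with c = 0). The
# nutrient dependence of interference is encoded phenomenologically: `c`
# may differ between media; this is an assumption of the generator, not a
# mechanistic finding.
#
# Shared phage biology: adsorption a = 5e-9 ml/(cell.min), Erlang latent
# period tau = 35 min in m = 20 stages, burst size B = 50, free-phage decay
# 0.002/min, surface-mutant fraction 1e-5 per division. Media: high
# nutrient gives r_max = 0.025/min and carrying capacity 1e9 cells/ml; low
# nutrient r_max = 0.012/min and 3e8 cells/ml.

dms3vir_complete:
  description: >
    Fully effective interference: growth restored to no-phage levels at
    both doses in both nutrient conditions.
  phage_name: dms3vir
  phage: {a: 5.0e-9, tau: 35, m: 20, B: 50, delta_P: 0.002, mu: 1.0e-5}
  media:
    high_nutrient: {r_max: 0.025, K_N: 0.5, N0: 10, yield: 1.0e+8, c: 1.0}
    low_nutrient: {r_max: 0.012, K_N: 0.5, N0: 3, yield: 1.0e+8, c: 1.0}
  S0: 1.0e+7
  doses: {high: 1.0e+6, low: 1.0e+4, none: 0.0}
  replicates: {high_nutrient: 6, low_nutrient: 3}
  noise_sd: 0.005
  alpha_od: 1.0e-9

lbp1_intermediate_LB:
  description: >
    Partial interference in high-nutrient medium: the high-dose phage
    epidemic outruns the 23 h assay window, the 100-fold lower dose does
    not, so growth is restored at low but not high dose.
  phage_name: lbp1
  phage: {a: 5.0e-9, tau: 35, m: 20, B: 50, delta_P: 0.002, mu: 1.0e-5}
  media:
    high_nutrient: {r_max: 0.025, K_N: 0.5, N0: 10, yield: 1.0e+8, c: 0.972}
  S0: 1.0e+7
  doses: {high: 1.0e+6, low: 1.0e+4, none: 0.0}
  replicates: {high_nutrient: 6}
  noise_sd: 0.005
  alpha_od: 1.0e-9

lbp1_complete_M9:
  description: >
    The same phage in low-nutrient medium, where interference is strong
    enough to keep the epidemic subcritical: complete protection.
  phage_name: lbp1
  phage: {a: 5.0e-9, tau: 35, m: 20, B: 50, delta_P: 0.002, mu: 1.0e-5}
  media:
    low_nutrient: {r_max: 0.012, K_N: 0.5, N0: 3, yield: 1.0e+8, c: 0.999}
  S0: 1.0e+7
  doses: {high: 1.0e+6, low: 1.0e+4, none: 0.0}
  replicates: {low_nutrient: 3}
  noise_sd: 0.005
  alpha_od: 1.0e-9

phikz_none:
  description: >
    No effective interference (e.g. the phage shields its genome from the
    CRISPR machinery): the spacer-carrying strain behaves like the
    knock-out and is overwhelmed at both doses.
  phage_name: phikz
  phage: {a: 5.0e-9, tau: 35, m: 20, B: 50, delta_P: 0.002, mu: 1.0e-5}
  media:
    high_nutrient: {r_max: 0.025, K_N: 0.5, N0: 10, yield: 1.0e+8, c: 0.0}
  S0: 1.0e+7
  doses: {high: 1.0e+6, low: 1.0e+4, none: 0.0}
  replicates: {high_nutrient: 6}
  noise_sd: 0.005
  alpha_od: 1.0e-9
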