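# Illustrative parameter set for the murine DC-immunotherapy model.
#
# These are NOT fitted reference values. r, K, ef, T_death are main-text
# study values; every other constant is an order-of-magnitude choice from
# the murine CTL/DC/TGF-beta modelling literature, provided so the examples
# and pipeline run end to end. Replace with your own calibrated values for
# any scientific use.
#
# Units: cells and hours; TGF-beta in arbitrary concentration units
# consistent between e_supp and p_beta.
r: 0.00106          # maximal tumor growth rate, 1/h
K: 6.754e15         # tumor carrying capacity, cells
a_T: 5.0e-8         # maximal CTL killing efficiency, 1/(cell.h)
supp_floor: 0.69    # maximal TGF-beta reduction of killing, (0,1]
e_supp: 1.0e4       # Michaelis constant of TGF-beta suppression
mu_D: 0.0096        # DC decay rate, 1/h (~3-day half-life)
r_a: 0.05           # CTL activation rate, 1/h
r_e: 0.01           # activated-CTL expansion rate, 1/h
tau: 96             # activation/expansion delay, h
theta_D: 2.5e5      # Michaelis constant, DC effect on activation, cells
theta_a: 2.5e6      # Michaelis constant, CTL expansion, cells
mu_Ca: 0.007        # activated-CTL death rate, 1/h
mu_Ci: 0.0012       # naive-CTL death rate, 1/h
p_beta: 5.75e-6     # TGF-beta production per tumor cell, conc/(cell.h)
mu_beta: 0.14       # TGF-beta degradation rate, 1/h
ef: 0.5             # fraction of injected DCs reaching the lymph nodes
T_death: 1.6e10     # tumor burden at host death, cells
T_erad: 1           # eradication threshold, cells
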