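# Default configuration of the coupled signaling-and-mechanics model.
# Version: 1 (matches package defaults; loading an empty file is equivalent).
# Units are noted per key. Unknown keys are rejected at load time.

# --- tissue / coupling -------------------------------------------------------
alpha_catenin: 30        # molecules/node, per cell (1 value or 7: centre first)
jub_production: 250      # nM/min, per cell
jub_degradation: 1       # 1/min, free Jub decay
jub_K_scale: 60          # molecule-scale Jub K's -> cell nM scale
conv_nM: 2               # nM of Jub sites per (molecule/node) per region
kJWp: 0.002              # 1/(nM min), Wts binding to junctional Jub
kJWm: 0.2                # 1/min, Jub-Wts complex dissociation
kdJW: 0.2                # 1/min, Wts turnover inside the Jub-Wts complex
vinculin: 0              # relative Vinculin level
boundary_force: 0        # pN/node, + stretch / - compression
growth_enabled: no
g0: 0.01                 # 1/(nM min), growth gain above Y0
Y0: 4                    # nM, Yki reference for growth
rate_max: 0.02           # 1/min, growth-rate cap
horizon: 60              # min, coupled simulation horizon
dt_couple: 0.5           # min, coupling step
mech_relax: 30           # s, mechanical relaxation per step
center_swelling: 1       # initial centre-cell area scale (growth presets use 1.15)

# --- mechanics ---------------------------------------------------------------
edge_length: 1           # um, hexagon side
KN: 1500                 # pN/um, belt stiffness
KT: 1500                 # pN/um, transverse stiffness
Xi: 100                  # pN s/um, damping
FA_belt: 900             # pN, contractile force per belt edge
FA_transverse: 0         # pN

# --- three-state alpha-catenin (Bell rates) ---------------------------------
# Calibrated: C1-C2 crossover 4.5 pN, C2-C3 crossover 10 pN (at V = 0),
# settling 2-4 s near the first crossover, bound-Jub minimum in 5-9 pN.
bell:
  kf10: 2.245274         # 1/s  (= 0.25 * exp(9/4.1))
  ku10: 0.25             # 1/s
  kf20: 6.568704         # 1/s  (= 0.05 * exp(20/4.1))
  ku20: 0.05             # 1/s
  xf1: 1                 # nm
  xu1: 1                 # nm
  xf2: 1                 # nm
  xu2: 1                 # nm
  kBT: 4.1               # pN nm (25 C)
  KV: 2                  # Vinculin half-saturation (relative units)
  jub_K: [3.3333333, 50, 1.25]   # Jub dissociation constants for C1, C2, C3
  n_cat: 30              # molecules/node, default total alpha-catenin

# --- upstream Hippo network (nM, min) ---------------------------------------
hippo:
  ex_stabilization_mode: parallel   # or fat_stabilizes_ex
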