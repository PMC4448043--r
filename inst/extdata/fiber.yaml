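# Fiber scenario: 105 um core, NA 0.22 multimode fiber delivering
# 1.1 mW with its tip 300 um above the cortical surface in saline.
# Launch positions Gaussian (sigma = core radius / 2, truncated at the
# rim); directions uniform in solid angle inside the NA cone evaluated
# in saline.
run:
  n_photons: 1000000
  seed: 1
  step_cap: 100000
roulette:
  threshold: 1.0e-4
  survival: 0.1
  strict_termination: false
media:
  saline:
    refractive_index: 1.34
    mu_a: 0.0
    mu_s: 0.0
    g: 0.0
  tissue:
    refractive_index: 1.36
    mu_a: 0.07
    mu_s: 11.7
    g: 0.88
geometry:
  type: fiber_standoff
  standoff: 0.3
  domain_depth: 5.0
  domain_radius: 5.0
  tissue_medium: tissue
source:
  type: fiber
  core_diameter: 0.105
  na: 0.22
  sigma: 0.02625
  power: 1.1
  z_launch: -0.3
  na_reference: medium
grid:
  dr: 0.01
  dz: 0.01
  r_max: 1.5
  z_min: -0.4
  z_max: 2.0
analysis:
  thresholds: [0.5, 1.0, 2.0]
calibration:
  current_mA: [0.1, 4.0, 6.0]
  interface_mW_mm2: [0.5, 40.0, 52.0]
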