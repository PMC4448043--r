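# Micro-LED probe scenario: 30 um Lambertian disc emitting through a
# 100 um sapphire slab (laterally bounded at the 150 um probe width,
# reflecting contact behind the LED modelled as absorbing) into
# semi-infinite brain tissue.  All physical constants live here, not in
# code; grey-matter optical constants at 450 nm, sapphire and saline
# handbook indices.
run:
  n_photons: 1000000
  seed: 1
  step_cap: 100000
roulette:
  threshold: 1.0e-4
  survival: 0.1
  strict_termination: false
media:
  sapphire:
    refractive_index: 1.77
    mu_a: 0.0
    mu_s: 0.0
    g: 0.0
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
  type: mled_probe
  sapphire_thickness: 0.1
  probe_half_width: 0.075
  tissue_above: 0.0
  domain_depth: 5.0
  domain_radius: 5.0
  backplane_reflectivity: 0.0
  tissue_medium: tissue
source:
  type: led_disc
  diameter: 0.030
  z_launch: -0.1
  collimated: false
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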