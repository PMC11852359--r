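# Example run configuration for cytofem.
# Every key is optional; omitted keys keep the built-in defaults shown in
# default_config(). Units are SI and embedded in key names (Pa, m, N).
# Unknown keys are rejected.

scene:
  layout: single            # "single" (one cell) or "group" (18 cells)
  cell_radius_m: 1.0e-5     # cortex radius before the shape transform
  nucleus_radius_m: 5.0e-6
  single_box_m: 4.0e-5      # ECM box side for the single-cell scene (cube)
  group_nx: 3               # group grid: nx x ny x nz cells
  group_ny: 3
  group_nz: 2
  group_spacing_m: 2.5e-5   # center-to-center spacing (= grid cube side)
  group_pad_m: 1.25e-5      # ECM padding between cell block and box
  shape: sphere             # "sphere" or "oblate" (volume-preserving squash)
  oblate_squash: 0.6

materials:                  # per-component elastic constants
  ecm_variant: stiff        # "stiff" (alginate-like) or "soft" (medium-like)
  ecm_young_stiff_pa: 56200.0
  ecm_young_soft_pa: 30.0
  ecm_poisson: 0.4777
  cytoplasm_young_pa: 100.0
  cytoplasm_poisson: 0.37
  nucleus_young_pa: 400.0
  nucleus_poisson: 0.37
  membrane_young_pa: 1000.0       # cortex and nuclear membrane
  membrane_poisson: 0.3
  membrane_thickness_m: 6.0e-9
  actin_young_pa: 2.6e+9           # tendons
  actin_area_m2: 1.8e-17
  microtubule_young_pa: 1.2e+9     # bars
  microtubule_area_m2: 1.9e-16
  tendon_prestress_n: 9.0e-13     # pre-tension force per tendon

load:
  pressure_pa: 6.0          # dead load on the top (+z) box face, acting -z

solver:
  n_prestress_increments: 2 # step 1: prestress ramp, no pressure
  n_load_increments: 6      # step 2: pressure ramp
  rel_tol: 1.0e-8           # relative force-residual tolerance
  max_iterations: 20        # Newton cap per increment

resolution:                 # structured-mesh density knobs
  single_n_face: 5          # cube-surface divisions per face (single cell)
  single_layers: [2, 3, 4]  # radial layers: nucleus, cytoplasm, ECM shell
  group_n_face: 3
  group_layers: [1, 2, 2]
  padding_layers: 2         # layers between cell block and ECM box

output:
  dir: results
  write_vtu: false
  log_hmh_floor_pa: 1.0e-12 # clamp for the decimal-log HMH channel

seed: 1
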