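# Default reduced arterial tree: geometry and terminal-load constants.
#
# Reference state: adult of height 180 cm with a 33.2 mm ascending-aorta inlet
# and aortic distensibility 5.86e-3 /mmHg.  Per-segment distensibility is the
# aortic value times stiffness_ratio (peripheral vessels are stiffer).
# Terminal loads are three-element Windkessels; R_p_ratio fixes the relative
# split of peripheral resistance between beds (the absolute level is rescaled
# so the parallel total matches the requested TPR), R_c_fraction sets the
# characteristic resistance as a fraction of that bed's R_p, and C_t_ratio
# splits the total terminal compliance.
reference:
  height_cm: 180
  aortic_diameter_mm: 33.2
  distensibility: 5.86        # 1e-3 / mmHg
  terminal_Ct_total: 0.35     # ml/mmHg, split by C_t_ratio
  venous_pressure_mmHg: 5.0
segments:
  - id: ascending_aorta
    parent: ~
    length_cm: 6.0
    d_in_cm: 3.32
    d_out_cm: 3.10
    stiffness_ratio: 1.0
    n_elements: 2
  - id: aortic_arch_a
    parent: ascending_aorta
    length_cm: 3.5
    d_in_cm: 3.10
    d_out_cm: 2.90
    stiffness_ratio: 1.0
    n_elements: 2
  - id: aortic_arch_b
    parent: aortic_arch_a
    length_cm: 4.5
    d_in_cm: 2.90
    d_out_cm: 2.60
    stiffness_ratio: 1.0
    n_elements: 2
  - id: thoracic_aorta
    parent: aortic_arch_b
    length_cm: 16.0
    d_in_cm: 2.60
    d_out_cm: 2.00
    stiffness_ratio: 1.0
    n_elements: 3
  - id: abdominal_aorta
    parent: thoracic_aorta
    length_cm: 15.0
    d_in_cm: 2.00
    d_out_cm: 1.40
    stiffness_ratio: 0.9
    n_elements: 3
  - id: iliac
    parent: abdominal_aorta
    length_cm: 14.0
    d_in_cm: 1.20
    d_out_cm: 0.90
    stiffness_ratio: 0.5
    n_elements: 2
    terminal:
      R_p_ratio: 1.0
      R_c_fraction: 0.05
      C_t_ratio: 0.55
  - id: brachiocephalic
    parent: ascending_aorta
    length_cm: 3.5
    d_in_cm: 1.30
    d_out_cm: 1.10
    stiffness_ratio: 0.6
    n_elements: 2
  - id: right_subclavian
    parent: brachiocephalic
    length_cm: 16.0
    d_in_cm: 0.95
    d_out_cm: 0.55
    stiffness_ratio: 0.45
    n_elements: 2
    terminal:
      R_p_ratio: 3.44
      R_c_fraction: 0.05
      C_t_ratio: 0.16
  - id: left_carotid
    parent: aortic_arch_a
    length_cm: 17.0
    d_in_cm: 0.80
    d_out_cm: 0.60
    stiffness_ratio: 0.5
    n_elements: 2
    terminal:
      R_p_ratio: 3.24
      R_c_fraction: 0.05
      C_t_ratio: 0.17
  - id: left_subclavian
    parent: aortic_arch_b
    length_cm: 4.0
    d_in_cm: 0.95
    d_out_cm: 0.85
    stiffness_ratio: 0.5
    n_elements: 2
  - id: left_axillary
    parent: left_subclavian
    length_cm: 12.0
    d_in_cm: 0.85
    d_out_cm: 0.65
    stiffness_ratio: 0.4
    n_elements: 2
  - id: left_brachial
    parent: left_axillary
    length_cm: 12.0
    d_in_cm: 0.65
    d_out_cm: 0.45
    stiffness_ratio: 0.35
    n_elements: 2
    terminal:
      R_p_ratio: 4.58
      R_c_fraction: 0.05
      C_t_ratio: 0.12
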