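model:
  body_mass: 80.0
  height: 1.8
  belt_speed: 1.18
  gravity: 9.81
  added_mass:
    shank: 0.3
    foot: 0.5
  mtp_stiffness: 15.0
  mtp_damping: 0.8
contact:
  normal_stiffness: 600000.0
  normal_damping: 2.0
  friction_coefficient: 1.0
  velocity_smoothing: 0.01
  exponent: 1.5
gains:
  hip:
    kp: 2400.0
    ki: 150.0
    kd: 110.0
  knee:
    kp: 1800.0
    ki: 125.0
    kd: 60.0
  ankle:
    kp: 1400.0
    ki: 125.0
    kd: 40.0
  hat_upright:
    kp: 5000.0
    kd: 800.0
  integrator_limit: 60.0
reference:
  cycle_duration: 1.21
  speed: 1.18
  n_cycles: 4.0
exo:
  stiffness: 4.85
  engage_phase: 29.0
  disengage_phase: 53.0
  enabled: yes
  geometry:
    anchor_position:
    - 1.0
    - 0.05
    spool_axis_local:
    - -0.065
    - -0.045
    shank_attachment_local:
    - -0.065
    - -0.16
    spool_ratio: 5.0
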