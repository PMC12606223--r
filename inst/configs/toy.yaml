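# Single-joint two-muscle toy movement.
scenario: toy
kind: toy
duration: 0.6
dt: 1.0e-4
toy:
  excursion: 0.5               # joint excursion (rad)
  T: 0.4                       # reference movement time (s)
  inertia: 0.05                # load inertia about the hinge (kg m^2)
  act_tau: 0.02
  muscle: {d1: 4, d2: 1.8, d3: 30.24, v_max: 1.0, r: 0.05, F_max: 300}
  gains: {Kp: 15, Kd: 2.5}
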