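# Cross-body (contralateral) reach condition.
scenario: cross_body
kind: reach
duration: 0.7
dt: 1.0e-4
reach:
  T: 0.35                      # reference movement time (s)
  target: [-0.30, 0.35]        # cross-body (contralateral) target (m)
  wrist_final: -0.15           # final wrist angle (rad): slight extension
  initial_posture_deg: [10, 120, 0]   # shoulder, elbow, wrist flexion angles
  target_tolerance: 0.01       # reach tolerance (m)
gains:
  Kp: [60, 60, 60]             # excitation per rad of joint error
  Kd: [8, 8, 8]                # excitation per rad/s of error rate
model:
  lengths: [0.30, 0.30, 0.15]  # upper arm, forearm, hand (m)
  masses: [2.0, 1.5, 0.5]      # kg; COM mid-segment, rod-like inertias
  act_tau: 0.02                # activation cascade stage time constant (s)
  muscles:
    shoulder: {d1: 4, d2: 1.8, d3: 30.24, v_max: 1.0, r: 0.05, F_max: 600}
    elbow:    {d1: 4, d2: 1.8, d3: 30.24, v_max: 1.0, r: 0.05, F_max: 400}
    wrist:    {d1: 4, d2: 1.8, d3: 30.24, v_max: 0.6, r: 0.03, F_max: 150}
perturbation: null
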