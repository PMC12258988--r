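name: fig2_nocan
figure: "2A/2B"
note: >
  Control with the CAN current removed (g_CAN = 0): onset and offset
  transitions occur at the same injected current, no hysteresis.
expect: tonic
params:
  g_CAN: 0
assumed:
  g_KCa: 0.5
  g_Kv1.2: 0.1
  K_out: 8.2
protocol:
  type: ramp
  max_I: 4
  phase_duration: 5000
analysis:
  type: hysteresis
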