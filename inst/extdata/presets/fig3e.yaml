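name: fig3e
figure: "3E"
note: >
  Reducing g_KCa further widens the hysteresis interval.
expect: bistable
params: {}
assumed:
  g_CAN: 0.65
  g_KCa: 0.1
protocol:
  type: ramp
  max_I: 4
  phase_duration: 5000
analysis:
  type: hysteresis
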