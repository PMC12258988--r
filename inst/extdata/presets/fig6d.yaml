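name: fig6d
figure: "6D"
note: >
  Raising g_NaP to 0.45 (printed) adds a subthreshold depolarizing drive that
  recruits the CaL-CICR-CAN loop and uncovers a hysteresis interval.
expect: bistable
params:
  g_KCa: 0.5
  g_NaP: 0.45
assumed:
  g_CAN: 0.55
protocol:
  type: ramp
  max_I: 3
  phase_duration: 5000
analysis:
  type: hysteresis
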