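name: fig6e
figure: "6E"
note: >
  Step validation of the NaP-facilitated bistable range.
expect: bistable
params:
  g_KCa: 0.5
  g_NaP: 0.45
assumed:
  g_CAN: 0.55
protocol:
  type: step
  I_mid: 0.73
  I_high: 2
  dwell: 2000
analysis:
  type: step_check
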