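name: fig8f
figure: "8F (step)"
note: >
  Step validation of the sodium-based bistable range at 12 mM potassium.
expect: bistable
params:
  g_CAN: 0
  K_out: 12
assumed:
  g_NaP: 0.4
protocol:
  type: step
  I_mid: 0.62
  I_high: 1.5
  dwell: 2000
analysis:
  type: step_check
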