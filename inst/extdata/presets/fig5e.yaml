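name: fig5e
figure: "5E"
note: >
  Step validation of the potassium-unmasked bistable range at 8 mM.
expect: bistable
params:
  g_KCa: 0.5
  K_out: 8
assumed:
  g_CAN: 0.55
protocol:
  type: step
  I_mid: 1.0
  I_high: 2.5
  dwell: 2000
analysis:
  type: step_check
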