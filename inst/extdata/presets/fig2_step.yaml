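name: fig2_step
figure: "2E"
note: >
  Step validation of the ramp-detected bistable range: plateaus
  0, 1.5, 3, 1.5, 0 uA/cm2 (printed). The cell is silent on the first
  1.5 plateau and keeps firing on the second, after activation at 3.
expect: bistable
params:
  g_CAN: 0.5
assumed:
  g_KCa: 0.5
  g_Kv1.2: 0.1
  K_out: 8.2
protocol:
  type: step
  I_mid: 1.5
  I_high: 3
  dwell: 2000
analysis:
  type: step_check
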