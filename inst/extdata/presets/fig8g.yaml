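name: fig8g
figure: "8G"
note: >
  At g_NaP = 0.25 (printed) sodium-based bistability appears once
  extracellular potassium reaches about 12 mM.
expect: bistable
params:
  g_CAN: 0
  g_NaP: 0.25
  K_out: 12
protocol:
  type: ramp
  max_I: 2
  phase_duration: 5000
analysis:
  type: hysteresis
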