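name: fig5d
figure: "5D"
note: >
  Raising extracellular potassium to 8 mM (printed) depolarizes E_K, weakens
  the SK current and unmasks bistability at the same g_CAN.
expect: bistable
params:
  g_KCa: 0.5
  K_out: 8
assumed:
  g_CAN: 0.55
protocol:
  type: ramp
  max_I: 3
  phase_duration: 5000
analysis:
  type: hysteresis
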