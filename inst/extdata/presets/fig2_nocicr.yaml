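name: fig2_nocicr
figure: "2F"
note: >
  Control with calcium-induced calcium release removed (k_CICR = 0, printed):
  the effective calcium clearance time constant collapses from 250 ms to the
  raw pump constant 10 ms, the CAN current stays weak, and the ramp
  hysteresis vanishes.
expect: tonic
params:
  g_CAN: 0.5
  k_CICR: 0
assumed:
  g_KCa: 0.5
  g_Kv1.2: 0.1
  K_out: 8.2
protocol:
  type: ramp
  max_I: 3
  phase_duration: 5000
analysis:
  type: hysteresis
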