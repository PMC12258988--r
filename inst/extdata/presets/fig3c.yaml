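name: fig3c
figure: "3C"
note: >
  SK current dominant (printed g_KCa = 0.5): no hysteresis. The g_CAN value
  of the panel is not printed; 0.65 (assumed) sits below this
  implementation's bistability boundary at g_KCa = 0.5.
expect: tonic
params:
  g_KCa: 0.5
assumed:
  g_CAN: 0.65
protocol:
  type: ramp
  max_I: 4
  phase_duration: 5000
analysis:
  type: hysteresis
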