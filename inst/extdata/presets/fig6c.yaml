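name: fig6c
figure: "6C"
note: >
  No persistent sodium current (g_NaP = 0, printed): the CAN current alone is
  below the bistability boundary at this g_CAN. The figure's g_CAN = 0.9 is
  replaced by 0.55 (assumed) for the same reason as in the potassium presets.
expect: tonic
params:
  g_KCa: 0.5
  g_NaP: 0
assumed:
  g_CAN: 0.55
protocol:
  type: ramp
  max_I: 4
  phase_duration: 5000
analysis:
  type: hysteresis
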