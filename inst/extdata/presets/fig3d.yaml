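name: fig3d
figure: "3D"
note: >
  Reducing g_KCa at fixed g_CAN unmasks bistability: intermediate SK level.
expect: bistable
params: {}
assumed:
  g_CAN: 0.65
  g_KCa: 0.25
protocol:
  type: ramp
  max_I: 4
  phase_duration: 5000
analysis:
  type: hysteresis
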