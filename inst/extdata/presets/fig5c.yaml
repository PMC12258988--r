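name: fig5c
figure: "5C"
note: >
  Normal extracellular potassium (4 mM, printed; g_KCa = 0.5 printed): E_K
  is strongly negative, the SK current efficiently opposes the CAN current,
  no bistability. The figure's g_CAN = 0.9 is replaced by 0.55 (assumed):
  in this implementation the bistability boundary at 4 mM sits below 0.9,
  so 0.55 is used to demonstrate the same potassium switch.
expect: tonic
params:
  g_KCa: 0.5
  K_out: 4
assumed:
  g_CAN: 0.55
protocol:
  type: ramp
  max_I: 4
  phase_duration: 5000
analysis:
  type: hysteresis
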