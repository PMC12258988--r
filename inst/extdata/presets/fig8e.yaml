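name: fig8e
figure: "8E/8F"
note: >
  Elevated potassium (12 mM, printed) attenuates the post-spike
  hyperpolarization; I_NaP stays engaged between spikes and a pure
  sodium-based hysteresis interval opens (about 0.4 to 0.85 uA/cm2 here,
  matching the printed 0.45-0.85 interval).
expect: bistable
params:
  g_CAN: 0
  K_out: 12
assumed:
  g_NaP: 0.4
protocol:
  type: ramp
  max_I: 2
  phase_duration: 5000
analysis:
  type: hysteresis
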