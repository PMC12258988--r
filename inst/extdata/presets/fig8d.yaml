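name: fig8d
figure: "8D"
note: >
  Persistent sodium current without the CAN current (g_CAN = 0, printed) at
  normal potassium (4 mM): the deep post-spike hyperpolarization deactivates
  I_NaP between spikes, onset and offset coincide, no bistability. The
  panel's g_NaP is not printed; 0.4 assumed (it reproduces the printed
  rest-loss current of about 0.85 uA/cm2 at 12 mM).
expect: tonic
params:
  g_CAN: 0
  K_out: 4
assumed:
  g_NaP: 0.4
protocol:
  type: ramp
  max_I: 2
  phase_duration: 5000
analysis:
  type: hysteresis
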