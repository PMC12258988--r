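name: fig9b
figure: "9B"
note: >
  Kv1.2 present (g_Kv1.2 = 2, printed), SK absent: the pulse first stalls
  below threshold for seconds while Kv1.2 slowly inactivates, then firing
  starts (delayed excitation). In this implementation the discharge after the
  delayed onset holds a steady rate; the accelerating (ramping) rate of the
  source panel is not reproduced by the printed kinetics. Pulse amplitude
  10.75 uA/cm2 assumed, inside the delayed-excitation window; 100 ms rounded
  onset avoids a spurious spike on the step edge.
expect: delayed
params:
  g_CAN: 0
  g_NaP: 0
  g_KCa: 0
  g_Kv1.2: 2
protocol:
  type: pulse
  amplitude: 10.75
  pre: 500
  onset_ramp: 100
  duration: 20000
  post: 500
analysis:
  type: rate
  window: train
  train_span: 4000
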