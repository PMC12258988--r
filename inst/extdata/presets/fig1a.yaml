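name: fig1a
figure: "1A"
note: >
  Brief suprathreshold pulse with SK current dominant and the CAN current
  absent: the calcium transient drives a slow afterhyperpolarization.
  Printed: g_KCa = 0.5, g_CAN = 0. The pulse amplitude/timing are not printed
  and are assumed.
expect: AHP
params:
  g_KCa: 0.5
  g_CAN: 0
protocol:
  type: pulse
  amplitude: 3.5
  pre: 1000
  duration: 500
  post: 8000
analysis:
  type: sadp
  window: 7500
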