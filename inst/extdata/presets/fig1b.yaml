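name: fig1b
figure: "1B"
note: >
  Same pulse with the CAN current dominant (printed g_KCa = 0.5,
  g_CAN = 0.7): the calcium transient now drives a slow afterdepolarization
  that decays with the effective calcium clearance time constant.
expect: ADP
params:
  g_KCa: 0.5
  g_CAN: 0.7
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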