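name: fig9a
figure: "9A"
note: >
  SK current present, Kv1.2 absent: sustained depolarization produces spike
  frequency adaptation as intracellular calcium accumulates. The g_KCa value
  and pulse amplitude are not printed; 1 and 8 uA/cm2 assumed. The pulse has
  a 100 ms rounded onset so the response reflects the slow conductances
  rather than the step transient.
expect: adapting
params:
  g_CAN: 0
  g_NaP: 0
  g_Kv1.2: 0
assumed:
  g_KCa: 1
protocol:
  type: pulse
  amplitude: 8
  pre: 500
  onset_ramp: 100
  duration: 12000
  post: 500
analysis:
  type: rate
  window: stimulus
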