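name: fig2_ramp
figure: "2D"
note: >
  Slow triangular ramp 0 -> 3 -> 0 uA/cm2 revealing hysteresis between the
  spiking onset (I_up) and offset (I_down) thresholds with g_CAN = 0.5
  (printed). The figure does not print the background conductances or the
  extracellular potassium level; the assumed block fixes them so that the
  converged ramp reproduces the printed thresholds I_up = 1.7 and
  I_down = 1.1 uA/cm2.
expect: bistable
params:
  g_CAN: 0.5
assumed:
  g_KCa: 0.5
  g_Kv1.2: 0.1
  K_out: 8.2
protocol:
  type: ramp
  max_I: 3
  phase_duration: 5000
analysis:
  type: hysteresis
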