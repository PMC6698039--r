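open_cohort:
  p_adhesions:
    point: 0.889
    alpha: 80.0
    beta: 10.0
  p_asbo:
    point: 0.0856
    alpha: 199.0
    beta: 2127.0
  p_asbo_surgical:
    point: 0.032
    alpha: 74.0
    beta: 2252.0
  p_repeat_raw:
    point: 0.24
    alpha: 64.0
    beta: 200.0
lap_cohort:
  p_adhesions:
    point: 0.623
    alpha: 38.0
    beta: 23.0
  p_asbo:
    point: 0.0663
    alpha: 77.0
    beta: 1085.0
  p_asbo_surgical:
    point: 0.031
    alpha: 36.0
    beta: 1126.0
  p_repeat_raw:
    point: 0.24
    alpha: 64.0
    beta: 200.0
rr_adhesions:
  point: 0.51
  ci_low: 0.43
  ci_high: 0.61
rr_asbo:
  point: 0.68
  ci_low: 0.35
  ci_high: 1.32
rr_asbo_surgical:
  point: 0.49
  ci_low: 0.28
  ci_high: 0.88
cost_asbo_operative:
  mean: 18366.0
  sd: 2831.0
cost_asbo_conservative:
  mean: 2565.0
  sd: 299.0
cost_repeat_no_adhesions:
  mean: 14063.0
  sd: 812.0
cost_repeat_adhesions:
  mean: 18579.0
  sd: 1722.0
barrier_sheets:
  minimum: 2.0
  mode: 3.45
  maximum: 4.0
  unit_price: 190.812121212121212
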