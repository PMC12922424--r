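schema_version: 1
name: CDK4/6 BIA scenario 2 (ABMA & RIBO to 80%)
population:
  base_year: 2024
  base_count: 173.0
  incidence_rate: 0.1
  dropout_rate: 0.05
  horizon_years: 5
  rounding_policy: nearest_half_away_from_zero
arms:
- arm_id: abma_ribo
  label: ABMA & RIBO
  role: intervention
- arm_id: plbo_mix
  label: PLBO/Other Tx
  role: comparator_mix
- arm_id: std_care
  label: Current treatment mix
  role: comparator_mix
unit_costs:
- arm_id: abma_ribo
  year: 2024
  cost_qar: 171891.271676300588297
- arm_id: plbo_mix
  year: 2024
  cost_qar: 156664.27745664739632
- arm_id: abma_ribo
  year: 2025
  cost_qar: 171560.714285714289872
- arm_id: plbo_mix
  year: 2025
  cost_qar: 156363.003663003648398
- arm_id: abma_ribo
  year: 2026
  cost_qar: 171891.277486910985317
- arm_id: plbo_mix
  year: 2026
  cost_qar: 156664.272251308895648
- arm_id: abma_ribo
  year: 2027
  cost_qar: 171506.444699579034932
- arm_id: plbo_mix
  year: 2027
  cost_qar: 156313.532338308461476
- arm_id: abma_ribo
  year: 2028
  cost_qar: 171891.273696682445006
- arm_id: plbo_mix
  year: 2028
  cost_qar: 156664.26540284359362
- arm_id: std_care
  year: 2024
  cost_qar: 156664.27745664739632
- arm_id: std_care
  year: 2025
  cost_qar: 156363.0
- arm_id: std_care
  year: 2026
  cost_qar: 156664.277486910985317
- arm_id: std_care
  year: 2027
  cost_qar: 156313.537313432840165
- arm_id: std_care
  year: 2028
  cost_qar: 156664.279620853078086
scenarios:
  baseline:
    scenario_name: baseline (current mix)
    shares:
      '2024':
        std_care: 1.0
      '2025':
        std_care: 1.0
      '2026':
        std_care: 1.0
      '2027':
        std_care: 1.0
      '2028':
        std_care: 1.0
  projected:
    scenario_name: projected
    shares:
      '2024':
        abma_ribo: 0.3
        plbo_mix: 0.7
      '2025':
        abma_ribo: 0.4
        plbo_mix: 0.6
      '2026':
        abma_ribo: 0.5
        plbo_mix: 0.5
      '2027':
        abma_ribo: 0.65
        plbo_mix: 0.35
      '2028':
        abma_ribo: 0.8
        plbo_mix: 0.2
threshold:
  gdp_per_capita: 302172.0
  multiplier: 1.5
  override_value: 453822.0
  tolerance_fraction: 0.1
currency:
  reporting_currency: QAR
  usd_per_unit_rate: 3.65
  conversion_rounding: truncate_toward_zero
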