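schema_version: 1
name: CDK4/6 BIA scenario 1 (ABMA to 60%)
population:
  base_year: 2024
  base_count: 173.0
  incidence_rate: 0.1
  dropout_rate: 0.05
  horizon_years: 5
  rounding_policy: nearest_half_away_from_zero
arms:
- arm_id: abma
  label: ABMA
  role: intervention
- arm_id: cdk_mix
  label: PLBO/RIBO/Other Tx
  role: comparator_mix
- arm_id: std_care
  label: Current treatment mix
  role: comparator_mix
unit_costs:
- arm_id: abma
  year: 2024
  cost_qar: 144226.849710982642137
- arm_id: cdk_mix
  year: 2024
  cost_qar: 179911.929190751427086
- arm_id: abma
  year: 2025
  cost_qar: 143949.50549450548715
- arm_id: cdk_mix
  year: 2025
  cost_qar: 179565.941915227653226
- arm_id: abma
  year: 2026
  cost_qar: 144226.858638743433403
- arm_id: cdk_mix
  year: 2026
  cost_qar: 179911.928446771373274
- arm_id: abma
  year: 2027
  cost_qar: 143903.960199004970491
- arm_id: cdk_mix
  year: 2027
  cost_qar: 179509.144278606952867
- arm_id: abma
  year: 2028
  cost_qar: 144226.864139020530274
- arm_id: cdk_mix
  year: 2028
  cost_qar: 179911.919431279617129
- arm_id: std_care
  year: 2024
  cost_qar: 179911.924855491321068
- arm_id: std_care
  year: 2025
  cost_qar: 179565.939560439554043
- arm_id: std_care
  year: 2026
  cost_qar: 179911.926701570686419
- arm_id: std_care
  year: 2027
  cost_qar: 179509.134328358195489
- arm_id: std_care
  year: 2028
  cost_qar: 179911.924170616111951
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
        abma: 0.2
        cdk_mix: 0.8
      '2025':
        abma: 0.3
        cdk_mix: 0.7
      '2026':
        abma: 0.4
        cdk_mix: 0.6
      '2027':
        abma: 0.5
        cdk_mix: 0.5
      '2028':
        abma: 0.6
        cdk_mix: 0.4
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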