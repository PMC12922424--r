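# One-way sensitivity axes for the scenario-1 model:
# +/-10 percentage-point uptake shift and +/-10% / +/-25% cost factors.
- axis_id: uptake_pp
  target: uptake_trajectory
  levels: [-0.10, 0.10]
- axis_id: intervention_price
  target: arm_unit_cost
  arm_selector: [abma]
  scenario_scope: both
  levels: [-0.25, -0.10, 0.10, 0.25]
- axis_id: comparator_price
  target: arm_unit_cost
  arm_selector: [cdk_mix, std_care]
  scenario_scope: both
  levels: [-0.25, -0.10, 0.10, 0.25]
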