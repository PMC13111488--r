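arm,expected_cost_eur,expected_effect,is_baseline
fixed_appliance,2501,1,TRUE
removable_plate,1497,0.66,FALSE
quad_helix,1545,0.82,FALSE
extra_oral_traction,1686,0.57,FALSE
activator,1728,0.56,FALSE
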