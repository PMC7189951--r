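quantity,value
n_women,812
at_least_1_child,770
at_least_2_children,671
at_least_3_children,254
at_least_4_children,73
first_pregnancy_le18_at_first_delivery,163
first_delivery_denominator,770
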