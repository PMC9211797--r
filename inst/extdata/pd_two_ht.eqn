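28
inclusion_old_animate old r_a
inclusion_old_animate old (1-r_a)*f_a
inclusion_old_animate old (1-r_a)*(1-f_a)*gi_a
inclusion_old_animate new (1-r_a)*(1-f_a)*(1-gi_a)
exclusion_old_animate new r_a
exclusion_old_animate old (1-r_a)*f_a
exclusion_old_animate old (1-r_a)*(1-f_a)*ge_a
exclusion_old_animate new (1-r_a)*(1-f_a)*(1-ge_a)
inclusion_new_animate new d_a
inclusion_new_animate old (1-d_a)*gi_a
inclusion_new_animate new (1-d_a)*(1-gi_a)
exclusion_new_animate new d_a
exclusion_new_animate old (1-d_a)*ge_a
exclusion_new_animate new (1-d_a)*(1-ge_a)
inclusion_old_inanimate old r_i
inclusion_old_inanimate old (1-r_i)*f_i
inclusion_old_inanimate old (1-r_i)*(1-f_i)*gi_i
inclusion_old_inanimate new (1-r_i)*(1-f_i)*(1-gi_i)
exclusion_old_inanimate new r_i
exclusion_old_inanimate old (1-r_i)*f_i
exclusion_old_inanimate old (1-r_i)*(1-f_i)*ge_i
exclusion_old_inanimate new (1-r_i)*(1-f_i)*(1-ge_i)
inclusion_new_inanimate new d_i
inclusion_new_inanimate old (1-d_i)*gi_i
inclusion_new_inanimate new (1-d_i)*(1-gi_i)
exclusion_new_inanimate new d_i
exclusion_new_inanimate old (1-d_i)*ge_i
exclusion_new_inanimate new (1-d_i)*(1-ge_i)
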