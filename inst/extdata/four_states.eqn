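22
old_animate recollect r_a
old_animate familiar (1-r_a)*f_a
old_animate recollect (1-r_a)*(1-f_a)*gr_a
old_animate familiar (1-r_a)*(1-f_a)*(1-gr_a)*gf_a
old_animate guess (1-r_a)*(1-f_a)*(1-gr_a)*(1-gf_a)*gg_a
old_animate new (1-r_a)*(1-f_a)*(1-gr_a)*(1-gf_a)*(1-gg_a)
new_animate new d_a
new_animate recollect (1-d_a)*gr_a
new_animate familiar (1-d_a)*(1-gr_a)*gf_a
new_animate guess (1-d_a)*(1-gr_a)*(1-gf_a)*gg_a
new_animate new (1-d_a)*(1-gr_a)*(1-gf_a)*(1-gg_a)
old_inanimate recollect r_i
old_inanimate familiar (1-r_i)*f_i
old_inanimate recollect (1-r_i)*(1-f_i)*gr_i
old_inanimate familiar (1-r_i)*(1-f_i)*(1-gr_i)*gf_i
old_inanimate guess (1-r_i)*(1-f_i)*(1-gr_i)*(1-gf_i)*gg_i
old_inanimate new (1-r_i)*(1-f_i)*(1-gr_i)*(1-gf_i)*(1-gg_i)
new_inanimate new d_i
new_inanimate recollect (1-d_i)*gr_i
new_inanimate familiar (1-d_i)*(1-gr_i)*gf_i
new_inanimate guess (1-d_i)*(1-gr_i)*(1-gf_i)*gg_i
new_inanimate new (1-d_i)*(1-gr_i)*(1-gf_i)*(1-gg_i)
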