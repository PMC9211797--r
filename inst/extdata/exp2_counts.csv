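tree,category,count
inclusion_old_animate,old,1769
inclusion_old_animate,new,337
inclusion_old_inanimate,old,1685
inclusion_old_inanimate,new,421
inclusion_new_animate,old,316
inclusion_new_animate,new,1790
inclusion_new_inanimate,old,337
inclusion_new_inanimate,new,1769
exclusion_old_animate,old,597
exclusion_old_animate,new,1535
exclusion_old_inanimate,old,640
exclusion_old_inanimate,new,1492
exclusion_new_animate,old,256
exclusion_new_animate,new,1876
exclusion_new_inanimate,old,277
exclusion_new_inanimate,new,1855
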