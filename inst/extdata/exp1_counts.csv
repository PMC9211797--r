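tree,category,count
old_animate,recollect,2309
old_animate,familiar,1002
old_animate,guess,261
old_animate,new,828
old_inanimate,recollect,2112
old_inanimate,familiar,1100
old_inanimate,guess,308
old_inanimate,new,880
new_animate,recollect,88
new_animate,familiar,308
new_animate,guess,220
new_animate,new,3784
new_inanimate,recollect,132
new_inanimate,familiar,396
new_inanimate,guess,264
new_inanimate,new,3608
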