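class,automated,manual
kangaroo,21,0
car,9,0
human,3,0
other,40,51
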