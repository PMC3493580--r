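system,temperature,ddmu,se
1a,300,16,12
1b,300,0,0
2,300,79,26
1a,323,11,16
1b,323,3,16
2,323,75,26
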