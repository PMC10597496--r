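name,kind,weight_exc,weight_inh,tau_exc,tau_inh
base,HH,0.0002,0.0005,2,6
lw,HH,0.00015,0.0002,2,6
lt,HH,0.0002,0.0005,10,40
lwlt,HH,0.00015,0.0002,10,40
burst,HH,0.0001,0.0005,40,20
wb,WB,0.00003,0.00005,2,6
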