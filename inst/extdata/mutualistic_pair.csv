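# n_species 2
# n_mediators 2
# r0 0.080000000000000002,0.119999999999999996
# decay 0,0
# inhibition_law linear
# facilitation_law monod
# moser_n 1
# c_th 0
# k_default 10000
kind,species,mediator,value,depletable
production,1,1,0.10000000000000001,NA
production,2,2,0.10000000000000001,NA
influence,2,1,0.20000000000000001,TRUE
saturation,2,1,10000.00000000000000000,NA
consumption,2,1,1.00000000000000000,NA
influence,1,2,0.20000000000000001,TRUE
saturation,1,2,10000.00000000000000000,NA
consumption,1,2,1.00000000000000000,NA
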