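dataset,total_slices,synaptic_days,cellular_days,total_days,potential_days,total_size_tb,potential_size_tb
locust,8069,55.1,23.1,78.1,323.1,6.8,27.9
earwig,4039,7.9,3.4,11.3,76.7,1,6.6
praying_mantis,4302,27.8,4.7,32.4,84.9,2.8,7.3
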