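year,trap_type,n_traps,n_surveys,n_nonzero,n_mosquitoes,n_females
2014,CO2,666,28131,3951,39915,27208
2015,CO2,785,34447,6051,37746,24155
2016,CO2,794,37901,6560,44219,32132
2016,BG,19,278,105,377,254
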