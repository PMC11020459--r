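quantity,direct_cv,hb_cv
Minimum,0.2337,0.2338
1st quartile,1.8876,1.4892
Median,5.9076,3.3748
Mean,6.8314,3.6376
3rd quartile,8.9087,4.3265
Maximum,15.6256,4.5400
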