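year,n_calves,n_mothers,n_comparisons,mop,n_excluded,n_sampled_total
2006,8,32,256,4,0,61
2007,5,28,140,1,2,50
2008,7,28,196,2,5,67
2009,3,32,96,3,3,63
2010,6,24,144,4,1,54
2011,11,16,176,8,2,46
2012,4,10,40,2,2,27
2013,7,12,84,3,2,28
2014,7,8,56,5,1,26
2015,3,8,24,3,0,19
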