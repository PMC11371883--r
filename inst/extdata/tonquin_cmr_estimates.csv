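year,cmr_n_f,cmr_n_f_low,cmr_n_f_high,cmr_n_total,cmr_n_total_low,cmr_n_total_high
2006,41,41,41,65,65,65
2007,47,40,66,78,58,98
2008,48,42,67,87,72,102
2009,37,37,37,74,65,83
2010,28,28,28,55,55,55
2011,22,22,22,50,44,56
2012,14,14,14,37,26,48
2013,23,22,42,53,33,74
2014,16,15,31,35,29,41
2015,14,14,14,26,26,26
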