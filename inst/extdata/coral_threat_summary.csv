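tree_set,category,percent_species,D_mean,D_sd,pdelta_mean,pdelta_sd
scleractinia,en_plus,3.92,0.891,0.035,-0.263,0.278
scleractinia,vu_plus,32.70,0.897,0.019,-0.162,0.927
scleractinia,nt_plus,57.99,0.837,0.017,0.657,1.177
scleractinia,rare,11.77,0.966,0.024,1.387,0.954
scleractinia,bleaching,41.86,0.200,0.010,6.766,1.254
scleractinia,disease,30.96,0.069,0.011,6.706,1.083
scleractinia,cots,27.33,0.007,0.011,1.953,0.987
scleractinia,restricted_range,12.35,0.925,0.026,-1.033,0.378
mtdna,en_plus,2.03,0.359,0.069,-0.138,0.136
mtdna,vu_plus,23.19,0.731,0.025,-1.023,0.527
mtdna,nt_plus,50.14,0.763,0.019,0.774,0.979
mtdna,rare,3.77,1.038,0.061,-0.641,0.165
mtdna,bleaching,43.77,0.215,0.010,1.435,1.076
mtdna,disease,34.78,0.056,0.012,1.279,1.091
mtdna,cots,30.72,-0.100,0.011,-3.557,0.910
mtdna,restricted_range,4.06,0.845,0.047,-0.421,0.221
complex_clade,en_plus,4.74,0.876,0.059,-0.135,0.572
complex_clade,vu_plus,42.62,0.938,0.034,-1.521,1.965
complex_clade,nt_plus,63.79,0.909,0.033,-3.621,2.495
complex_clade,rare,13.37,0.975,0.038,2.868,1.976
complex_clade,bleaching,68.25,0.139,0.018,13.461,3.227
complex_clade,disease,53.48,0.055,0.020,10.994,2.589
complex_clade,cots,48.75,-0.122,0.017,3.422,2.539
complex_clade,restricted_range,12.26,0.912,0.048,-1.284,0.678
robust_clade,en_plus,3.04,0.881,0.041,-0.402,0.215
robust_clade,vu_plus,21.88,0.959,0.026,0.640,0.748
robust_clade,nt_plus,51.67,0.757,0.022,4.107,1.139
robust_clade,rare,10.03,0.950,0.033,0.238,0.659
robust_clade,bleaching,13.07,0.533,0.030,-1.177,0.502
robust_clade,disease,6.38,0.105,0.013,2.534,0.954
robust_clade,cots,3.95,0.849,0.087,-0.439,0.294
robust_clade,restricted_range,12.46,0.921,0.029,-0.959,0.481
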