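class,measure,WSELM_JT,WSELM_SN1,KMC_JT,KMC_SN1,SVC_JT,SVC_SN1
I01,hit_rate,25.50,25.88,28.88,28.50,32.88,33.25
I01,node_pct,54.24,48.91,51.09,53.79,49.72,69.87
I02,hit_rate,27.13,28.00,27.25,25.88,28.50,29.63
I02,node_pct,54.85,45.51,54.32,46.16,50.21,71.03
I03,hit_rate,27.25,27.63,28.38,26.63,24.13,27.50
I03,node_pct,57.59,57.26,62.97,63.13,54.79,74.82
I04,hit_rate,26.00,25.25,20.38,22.88,25.25,30.88
I04,node_pct,52.56,58.63,47.24,55.29,55.56,79.31
I05,hit_rate,22.13,23.00,24.63,23.50,21.13,23.00
I05,node_pct,63.01,68.76,69.84,71.63,52.32,73.99
I06,hit_rate,2.25,2.63,2.25,2.25,4.13,3.88
I06,node_pct,37.26,36.51,34.62,37.40,52.21,66.28
I07,hit_rate,3.75,3.38,3.00,2.75,3.63,4.00
I07,node_pct,52.22,55.82,49.81,50.19,53.32,74.41
I08,hit_rate,7.63,7.25,7.00,8.38,7.25,8.88
I08,node_pct,52.94,54.00,51.47,47.78,53.65,68.66
I09,hit_rate,3.75,4.25,3.88,4.25,4.38,5.25
I09,node_pct,42.60,46.38,39.71,37.76,52.71,67.00
I10,hit_rate,5.88,6.88,6.50,5.75,6.88,8.50
I10,node_pct,55.90,64.40,59.72,62.51,51.26,71.51
I11,hit_rate,4.50,6.50,5.13,6.38,6.13,6.00
I11,node_pct,50.57,55.26,50.28,54.00,51.32,69.66
I12,hit_rate,4.38,4.88,4.75,4.88,4.75,4.88
I12,node_pct,51.84,55.53,51.00,50.51,51.00,69.50
I13,hit_rate,6.38,6.75,6.63,6.63,6.88,6.75
I13,node_pct,51.84,56.22,48.25,47.44,52.12,71.26
I14,hit_rate,2.88,3.00,1.63,1.25,1.88,1.75
I14,node_pct,36.93,41.22,43.65,49.06,51.90,67.59
I15,hit_rate,8.63,8.50,8.25,8.13,9.13,8.25
I15,node_pct,62.90,67.49,67.78,69.82,54.74,71.01
I16,hit_rate,5.63,5.88,4.63,4.75,5.63,7.50
I16,node_pct,46.60,46.37,38.59,41.44,53.76,69.51
I17,hit_rate,9.88,10.88,10.00,11.00,12.00,11.50
I17,node_pct,60.29,66.09,56.71,59.06,52.68,71.53
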