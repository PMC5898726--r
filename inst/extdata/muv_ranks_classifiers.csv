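class,WSELM_JT,WSELM_SN1,KMC_JT,KMC_SN1,SVC_JT,SVC_SN1
I01,6.00,5.00,3.00,4.00,2.00,1.00
I02,5.00,3.00,4.00,6.00,2.00,1.00
I03,4.00,2.00,1.00,5.00,6.00,3.00
I04,2.00,3.50,6.00,5.00,3.50,1.00
I05,5.00,3.50,1.00,2.00,6.00,3.50
I06,5.00,3.00,5.00,5.00,1.00,2.00
I07,2.00,4.00,5.00,6.00,3.00,1.00
I08,3.00,4.00,6.00,2.00,5.00,1.00
I09,6.00,3.50,5.00,3.50,2.00,1.00
I10,5.00,2.50,4.00,6.00,2.50,1.00
I11,6.00,1.00,5.00,2.00,3.00,4.00
I12,6.00,2.00,4.50,2.00,4.50,2.00
I13,6.00,2.50,4.50,4.50,1.00,2.50
I14,2.00,1.00,5.00,6.00,3.00,4.00
I15,2.00,3.00,4.50,6.00,1.00,4.50
I16,3.50,2.00,6.00,5.00,3.50,1.00
I17,6.00,4.00,5.00,3.00,1.00,2.00
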