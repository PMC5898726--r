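class,C01,C02,C03,C04,C05,C06,C07,C08,C09,C10,C11,C12,C13,C14,C15,C16
I01,23.88,8.75,31.38,28.88,29.25,8.63,19.50,8.75,21.50,32.88,28.75,29.50,28.88,29.25,16.25,8.75
I02,28.63,13.25,33.38,31.13,31.38,13.25,16.75,13.25,24.00,34.50,31.50,31.75,31.13,32.13,19.13,13.25
I03,13.37,3.00,26.63,22.13,22.25,3.00,23.88,3.00,19.38,28.88,21.75,22.63,22.13,21.88,4.63,3.00
I04,16.50,5.88,20.75,18.63,18.75,6.00,9.13,5.88,12.50,22.63,19.00,18.88,18.63,19.25,8.88,5.88
I05,15.63,9.75,20.63,19.00,19.00,9.38,6.63,9.75,14.88,22.25,19.38,19.38,19.00,19.13,11.13,9.75
I06,0.75,1.50,2.75,2.13,2.38,1.38,4.00,1.50,0.25,3.25,1.88,2.38,2.13,2.13,0.25,1.50
I07,2.50,0.00,4.75,3.75,3.63,0.00,3.38,0.00,2.38,5.13,3.75,3.63,3.75,3.75,1.38,0.00
I08,0.75,0.00,6.88,3.50,3.50,0.00,4.13,0.00,1.50,8.38,3.00,3.75,3.50,3.38,0.25,0.00
I09,0.88,0.00,3.75,2.13,2.25,0.00,3.00,0.00,1.63,4.75,1.88,2.13,2.13,2.00,0.38,0.00
I10,2.00,2.50,5.13,3.50,3.63,2.50,5.38,2.50,3.75,6.25,3.63,3.75,3.50,3.75,0.50,2.50
I11,2.75,0.50,4.00,2.50,2.50,0.38,0.75,0.50,1.38,5.50,2.25,2.50,2.50,2.25,2.88,0.50
I12,2.63,0.50,3.25,2.63,2.63,0.50,1.63,0.50,1.88,4.38,2.63,2.63,2.63,2.63,1.75,0.50
I13,2.00,1.13,4.88,3.13,3.25,1.13,3.50,1.13,3.25,6.00,3.00,3.25,3.13,3.13,0.63,1.13
I14,1.75,0.50,1.88,1.75,1.50,0.50,0.75,0.50,1.13,1.88,1.75,1.63,1.75,1.63,0.88,0.50
I15,4.50,0.88,6.75,5.25,5.25,0.88,1.50,0.88,2.50,8.25,6.00,5.50,5.25,6.00,2.75,0.88
I16,0.50,0.00,4.13,2.88,2.88,0.00,4.50,0.00,1.75,5.88,2.13,2.75,2.88,2.25,0.13,0.00
I17,2.13,0.00,6.00,4.13,4.63,0.00,3.38,0.00,2.25,6.00,4.13,4.63,4.13,4.25,0.88,0.00
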