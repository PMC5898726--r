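class,C01,C02,C03,C04,C05,C06,C07,C08,C09,C10,C11,C12,C13,C14,C15,C16
I01,14.25,24.38,25.50,25.63,26.00,25.13,23.13,24.38,20.00,25.88,24.88,26.75,25.63,24.63,10.00,24.38
I02,14.00,26.50,27.13,28.63,28.13,27.50,24.00,26.50,25.25,28.00,29.13,28.25,28.63,29.50,9.50,26.50
I03,7.25,22.63,27.25,22.50,23.50,23.63,23.75,22.63,18.00,27.63,24.25,23.88,22.50,24.50,1.00,22.63
I04,8.50,20.50,26.00,19.63,20.88,20.00,22.13,20.50,20.50,25.25,21.13,21.25,19.63,22.88,5.63,20.50
I05,5.63,16.38,22.13,18.00,18.63,17.88,18.63,16.38,15.75,23.00,18.38,18.63,18.00,17.75,4.25,16.38
I06,1.75,2.50,2.25,2.00,2.13,2.88,3.63,2.50,2.13,2.63,1.75,2.13,2.00,1.25,2.38,2.50
I07,1.25,2.13,3.75,3.13,3.25,2.00,2.38,2.13,2.00,3.38,2.50,3.13,3.13,2.75,1.88,2.13
I08,2.75,3.63,7.63,4.88,5.50,4.25,5.63,3.63,5.50,7.25,5.38,6.13,4.88,5.88,0.75,3.63
I09,1.88,3.25,3.75,2.00,1.75,3.25,2.63,3.25,2.38,4.25,2.50,1.75,2.00,2.63,1.00,3.25
I10,1.25,4.75,5.88,3.75,4.38,5.50,3.63,4.75,3.25,6.88,3.63,4.50,3.75,5.13,2.13,4.75
I11,1.13,2.13,4.50,2.50,2.38,2.50,3.00,2.13,2.25,6.50,2.25,2.38,2.50,2.38,1.63,2.13
I12,2.13,2.38,4.38,3.63,3.38,3.00,3.88,2.38,2.63,4.88,3.63,3.50,3.63,3.63,2.00,2.38
I13,1.13,3.38,6.38,5.00,4.75,4.00,5.13,3.38,4.00,6.75,4.50,5.13,5.00,4.50,1.63,3.38
I14,2.13,1.00,2.88,2.25,2.25,1.50,1.88,1.00,2.00,3.00,2.75,2.13,2.25,2.75,1.75,1.00
I15,3.38,6.13,8.63,7.13,6.88,5.63,5.75,6.13,5.13,8.50,7.00,7.38,7.13,7.13,1.63,6.13
I16,3.63,6.25,5.63,3.75,3.88,5.38,4.00,6.25,3.75,5.88,3.38,4.25,3.75,3.38,4.13,6.25
I17,5.00,9.50,9.88,9.63,9.13,9.88,10.13,9.50,10.00,10.88,10.00,9.50,9.63,9.63,5.50,9.50
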