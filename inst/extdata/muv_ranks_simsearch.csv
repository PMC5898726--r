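class,C01,C02,C03,C04,C05,C06,C07,C08,C09,C10,C11,C12,C13,C14,C15,C16
I01,9.0,14.0,2.0,6.5,4.5,16.0,11.0,14.0,10.0,1.0,8.0,3.0,6.5,4.5,12.0,14.0
I02,9.0,14.5,2.0,7.5,6.0,14.5,12.0,14.5,10.0,1.0,5.0,4.0,7.5,3.0,11.0,14.5
I03,11.0,14.5,2.0,6.5,5.0,14.5,3.0,14.5,10.0,1.0,9.0,4.0,6.5,8.0,12.0,14.5
I04,9.0,15.0,2.0,7.5,6.0,13.0,11.0,15.0,10.0,1.0,4.0,5.0,7.5,3.0,12.0,15.0
I05,9.0,13.0,2.0,7.0,7.0,15.0,16.0,13.0,10.0,1.0,3.5,3.5,7.0,5.0,11.0,13.0
I06,14.0,11.0,3.0,7.0,4.5,13.0,1.0,11.0,15.5,2.0,9.0,4.5,7.0,7.0,15.5,11.0
I07,10.0,14.5,2.0,4.5,7.5,14.5,9.0,14.5,11.0,1.0,4.5,7.5,4.5,4.5,12.0,14.5
I08,11.0,14.5,2.0,6.0,6.0,14.5,3.0,14.5,10.0,1.0,9.0,4.0,6.0,8.0,12.0,14.5
I09,11.0,14.5,2.0,6.0,4.0,14.5,3.0,14.5,10.0,1.0,9.0,6.0,6.0,8.0,12.0,14.5
I10,15.0,12.5,3.0,9.5,7.5,12.5,2.0,12.5,5.0,1.0,7.5,5.0,9.5,5.0,16.0,12.5
I11,4.0,14.0,2.0,6.5,6.5,16.0,12.0,14.0,11.0,1.0,9.5,6.5,6.5,9.5,3.0,14.0
I12,6.0,14.5,2.0,6.0,6.0,14.5,12.0,14.5,10.0,1.0,6.0,6.0,6.0,6.0,11.0,14.5
I13,11.0,13.5,2.0,8.0,5.0,13.5,3.0,13.5,5.0,1.0,10.0,5.0,8.0,8.0,16.0,13.5
I14,4.5,14.5,1.5,4.5,9.0,14.5,12.0,14.5,10.0,1.5,4.5,7.5,4.5,7.5,11.0,14.5
I15,9.0,14.5,2.0,7.0,7.0,14.5,12.0,14.5,11.0,1.0,3.5,5.0,7.0,3.5,10.0,14.5
I16,11.0,14.5,3.0,5.0,5.0,14.5,2.0,14.5,10.0,1.0,9.0,7.0,5.0,8.0,12.0,14.5
I17,11.0,14.5,1.5,7.0,3.5,14.5,9.0,14.5,10.0,1.5,7.0,3.5,7.0,5.0,12.0,14.5
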