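class,C01,C02,C03,C04,C05,C06,C07,C08,C09,C10,C11,C12,C13,C14,C15,C16
I01,15.0,11.0,6.0,4.5,2.0,7.0,13.0,11.0,14.0,3.0,8.0,1.0,4.5,9.0,16.0,11.0
I02,15.0,11.0,9.0,3.5,6.0,8.0,14.0,11.0,13.0,7.0,2.0,5.0,3.5,1.0,16.0,11.0
I03,15.0,10.0,2.0,12.5,8.0,7.0,6.0,10.0,14.0,1.0,4.0,5.0,12.5,3.0,16.0,10.0
I04,15.0,9.5,1.0,13.5,7.0,12.0,4.0,9.5,9.5,2.0,6.0,5.0,13.5,3.0,16.0,9.5
I05,15.0,12.0,2.0,7.5,4.0,9.0,4.0,12.0,14.0,1.0,6.0,4.0,7.5,10.0,16.0,12.0
I06,14.5,5.0,8.0,12.5,10.0,2.0,1.0,5.0,10.0,3.0,14.5,10.0,12.5,16.0,7.0,5.0
I07,16.0,11.0,1.0,5.0,3.0,13.5,9.0,11.0,13.5,2.0,8.0,5.0,5.0,7.0,15.0,11.0
I08,15.0,13.0,1.0,9.5,6.5,11.0,5.0,13.0,6.5,2.0,8.0,3.0,9.5,4.0,16.0,13.0
I09,13.0,4.5,2.0,11.5,14.5,4.5,7.5,4.5,10.0,1.0,9.0,14.5,11.5,7.5,16.0,4.5
I10,16.0,6.0,2.0,10.5,9.0,3.0,12.5,6.0,14.0,1.0,12.5,8.0,10.5,4.0,15.0,6.0
I11,16.0,13.0,2.0,5.0,8.0,5.0,3.0,13.0,10.5,1.0,10.5,8.0,5.0,8.0,15.0,13.0
I12,15.0,13.0,2.0,5.5,9.0,10.0,3.0,13.0,11.0,1.0,5.5,8.0,5.5,5.5,16.0,13.0
I13,16.0,13.0,2.0,5.5,7.0,10.5,3.5,13.0,10.5,1.0,8.5,3.5,5.5,8.5,15.0,13.0
I14,8.5,15.0,2.0,6.0,6.0,13.0,11.0,15.0,10.0,1.0,3.5,8.5,6.0,3.5,12.0,15.0
I15,15.0,10.0,1.0,5.0,8.0,13.0,12.0,10.0,14.0,2.0,7.0,3.0,5.0,5.0,16.0,10.0
I16,14.0,2.0,5.0,12.0,10.0,6.0,9.0,2.0,12.0,4.0,15.5,7.0,12.0,15.5,8.0,2.0
I17,16.0,11.5,5.5,8.0,14.0,5.5,2.0,11.5,3.5,1.0,3.5,11.5,8.0,8.0,15.0,11.5
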