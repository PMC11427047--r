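id,side,lead_model,label,cathodes,anodes,amplitude,unit,frequency_hz,pulse_width_us
1,left,medtronic_3389,clinical,"1,2",case,5,V,130,60
1,left,medtronic_3389,ventral,1,case,3,V,120,60
1,left,medtronic_3389,dorsal,3,case,3,V,120,60
1,right,medtronic_3389,clinical,"1,2",case,4.5,V,125,60
1,right,medtronic_3389,ventral,1,case,3,V,120,60
1,right,medtronic_3389,dorsal,3,case,3,V,120,60
2,left,medtronic_3389,clinical,2,case,3.6,V,180,60
2,left,medtronic_3389,ventral,2,case,2,V,120,60
2,left,medtronic_3389,dorsal,3,case,2,V,120,60
2,right,medtronic_3389,clinical,2,case,3.5,V,180,60
2,right,medtronic_3389,ventral,2,case,2,V,120,60
2,right,medtronic_3389,dorsal,3,case,2,V,120,60
3,right,abbott_6172,clinical,"2a,2b,2c",case,4,mA,130,90
3,right,abbott_6172,ventral,"2b,2c",case,3,mA,120,60
3,right,abbott_6172,dorsal,4,case,3,mA,120,60
4,left,medtronic_3389,clinical,2,case,3.5,V,130,60
4,left,medtronic_3389,ventral,1,case,2,V,120,60
4,left,medtronic_3389,dorsal,2,case,2,V,120,60
5,left,abbott_6172,clinical,3c,case,3,mA,200,90
5,left,abbott_6172,ventral,2c,case,1,mA,120,60
5,left,abbott_6172,dorsal,4,case,2,mA,120,60
5,right,abbott_6172,clinical,"3a,3b,3c",case,4,mA,200,90
5,right,abbott_6172,ventral,2b,case,1,mA,120,60
5,right,abbott_6172,dorsal,4,case,2,mA,120,60
6,right,abbott_6172,clinical,"2a,2b,2c",case,3.8,mA,130,60
6,right,abbott_6172,ventral,"2a,2b",case,2.5,mA,120,60
6,right,abbott_6172,dorsal,4,case,2.5,mA,120,60
7,left,abbott_6172,clinical,"3a,3b,3c",case,3.7,mA,130,90
7,left,abbott_6172,ventral,2b,case,2,mA,120,60
7,left,abbott_6172,dorsal,3b,case,2,mA,120,60
7,right,abbott_6172,clinical,"2a,2b,2c",case,3.7,mA,130,90
7,right,abbott_6172,ventral,2a,case,2,mA,120,60
7,right,abbott_6172,dorsal,3a,case,2,mA,120,60
8,left,abbott_6172,clinical,"2a,2b,2c",case,4,mA,130,60
8,left,abbott_6172,ventral,"3b,3c",case,4,mA,120,60
8,left,abbott_6172,dorsal,4,case,4,mA,120,60
8,right,abbott_6172,clinical,"2a,2b,2c",case,4,mA,130,60
8,right,abbott_6172,ventral,"2a,2c",case,4,mA,120,60
8,right,abbott_6172,dorsal,"3a,3b,3c",case,4,mA,120,60
9,left,medtronic_3389,clinical,2,3,3.7,V,130,90
9,left,medtronic_3389,ventral,2,case,2,V,120,60
9,left,medtronic_3389,dorsal,3,case,2,V,120,60
9,right,medtronic_3389,clinical,2,case,3.7,mA,130,90
9,right,medtronic_3389,ventral,1,case,2,V,120,60
9,right,medtronic_3389,dorsal,3,case,2,V,120,60
10,left,medtronic_3389,clinical,2,case,3.4,V,130,60
10,left,medtronic_3389,ventral,0,case,2,V,120,60
10,left,medtronic_3389,dorsal,2,case,2,V,120,60
10,right,medtronic_3389,clinical,1,case,2.8,V,130,60
10,right,medtronic_3389,ventral,1,case,2,V,120,60
10,right,medtronic_3389,dorsal,3,case,2,V,120,60
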