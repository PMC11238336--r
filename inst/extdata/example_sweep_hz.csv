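f_Hz,Gp_Pa,Gpp_Pa
0.049974652,2.4103324,0.55964625
0.066642270,2.3135108,0.70896293
0.088868895,2.6322946,0.84832737
0.118508576,2.4195183,0.98402035
0.158033726,2.6281362,1.29664850
0.210741361,2.8917293,1.61145998
0.281028121,2.6828727,2.11879217
0.374757022,3.1270381,2.58820047
0.499746521,3.4499214,3.10973805
0.666422697,3.7679060,3.48273618
0.888688949,4.2629610,4.13206005
1.185085760,4.7440154,5.24942326
1.580337260,5.2581230,7.00010959
2.107413606,6.4834011,8.17525526
2.810281211,6.6582153,10.13513255
3.747570225,8.0667870,11.79676465
4.997465213,9.9750870,14.01810473
6.664226968,11.3038442,18.64784031
8.886889491,13.3195276,21.98202063
11.850857601,16.1518769,26.16910566
15.803372601,19.1866671,33.40345814
21.074136064,22.6708419,42.29503587
28.102812105,28.2498183,51.73555586
37.475702246,33.6192964,63.64968872
49.974652131,39.6875594,73.59602652
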