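# label: example batch A
# strain_amplitude: 0.01
# direction: up
frequency,g_prime,g_double_prime
0.31400000000000000,2.4103323804732981,0.55964625236688170
0.41872572969928368,2.3135108053790061,0.70896292708213948
0.55837973475222169,2.6322945993593994,0.84832736877946768
0.74461134357775971,2.4195182966977971,0.98402035374001118
0.99295518529287097,2.6281362389995273,1.29664850198014991
1.32412702076574806,2.8917293288318149,1.61145998114375355
1.76575176109769605,2.6828727339978067,2.11879217449145463
2.35466781730391039,3.1270380753440596,2.58820047467659542
3.13999999999999924,3.4499213763376946,3.10973804901982920
4.18725729699283722,3.7679060093998187,3.48273617581027928
5.58379734752221513,4.2629609852637627,4.13206005258555287
7.44611343577759577,4.7440153748154099,5.24942326221280098
9.92955185292870901,5.2581230062564055,7.00010959479342620
13.24127020765747709,6.4834011059761378,8.17525525880468962
17.65751761097694938,6.6582153166830134,10.13513254669326002
23.54667817303910837,8.0667870426147310,11.79676464607432962
31.39999999999998437,9.9750869578004391,14.01810473456852435
41.87257296992834199,11.3038442378152464,18.64784030980236906
55.83797347522216370,13.3195276316435081,21.98202062810188195
74.46113435777593281,16.1518769321022369,26.16910566395796423
99.29551852928702260,19.1866671412558567,33.40345814239505273
132.41270207657478863,22.6708418778591820,42.29503586973412865
176.57517610976950095,28.2498183368896001,51.73555585704986015
235.46678173039092030,33.6192963758402072,63.64968871626070523
313.99999999999994316,39.6875594019148181,73.59602652435148684
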