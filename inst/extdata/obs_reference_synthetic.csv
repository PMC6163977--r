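time_s,stress_Pa,strain,strain_var
0.00000000000000000,0.000000000000,0.013709584471466685,1e-04
0.10000000000000001,100000.000000000000,0.094703466605594866,1e-04
0.20000000000000001,200000.000000000000,0.205034857338151244,1e-04
0.30000000000000004,300000.000000000058,0.309490641061446525,1e-04
0.40000000000000002,400000.000000000000,0.409671058360789597,1e-04
0.50000000000000000,500000.000000000000,0.507743971813150008,1e-04
0.60000000000000009,600000.000000000116,0.627810286639649551,1e-04
0.70000000000000007,700000.000000000116,0.716353823415455837,1e-04
0.80000000000000004,800000.000000000000,0.842807949324710259,1e-04
0.90000000000000002,900000.000000000000,0.928040239571071068,1e-04
1.00000000000000000,1000000.000000000000,1.048482499832235959,1e-04
1.10000000000000009,899999.999999999884,0.970533834488606306,1e-04
1.20000000000000018,799999.999999999767,0.844735105174816314,1e-04
1.30000000000000004,700000.000000000000,0.765512526131413074,1e-04
1.40000000000000013,599999.999999999884,0.675361853301323256,1e-04
1.50000000000000000,500000.000000000000,0.590164720954765687,1e-04
1.60000000000000009,399999.999999999884,0.486785845915218673,1e-04
1.70000000000000018,299999.999999999825,0.367597460802788156,1e-04
1.80000000000000004,199999.999999999942,0.272998903939022597,1e-04
1.90000000000000013,99999.999999999869,0.212551581776857540,1e-04
2.00000000000000000,0.000000000000,0.096933614059215245,1e-04
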