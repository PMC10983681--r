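period,node,actual,forecast
2019-01,Total,5724,6540
2019-02,Total,8299,7876
2019-03,Total,10812,9268
2019-04,Total,7519,5610
2019-05,Total,9067,7464
2019-06,Total,10439,8377
2019-07,Total,9493,7865
2019-08,Total,6418,5496
2019-09,Total,8474,8117
2019-10,Total,6586,8075
2019-11,Total,5914,6748
2019-12,Total,7131,6507
2020-01,Total,5600,6540
2020-02,Total,7900,7876
2020-03,Total,8850,9267
2020-04,Total,2350,5610
2020-05,Total,2000,7464
2020-06,Total,3500,8377
2020-07,Total,2550,7865
2020-08,Total,3700,5496
2020-09,Total,3850,8117
2020-10,Total,5600,8075
2020-11,Total,5950,6748
2020-12,Total,5900,6507
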