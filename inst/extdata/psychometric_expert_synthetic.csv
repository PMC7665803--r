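"location_mm","mean_lick_prob","sd","n"
0.125,0.9163,0.0526,15
0.375,0.9151,0.0534,15
0.625,0.9135,0.0546,15
0.875,0.9115,0.056,15
1.125,0.9088,0.0577,15
1.375,0.9053,0.0597,15
1.625,0.9007,0.062,15
1.875,0.8947,0.0648,15
2.125,0.8869,0.0678,15
2.375,0.8769,0.0711,15
2.625,0.864,0.0747,15
2.875,0.8476,0.0784,15
3.125,0.827,0.0822,15
3.375,0.8014,0.0859,15
3.625,0.7702,0.0895,15
3.875,0.7329,0.0927,15
4.125,0.6895,0.0954,15
4.375,0.6402,0.0976,15
4.625,0.5863,0.0991,15
4.875,0.5291,0.0999,15
5.125,0.4709,0.0999,15
5.375,0.4137,0.0991,15
5.625,0.3598,0.0976,15
5.875,0.3105,0.0954,15
6.125,0.2671,0.0927,15
6.375,0.2298,0.0895,15
6.625,0.1986,0.0859,15
6.875,0.173,0.0822,15
7.125,0.1524,0.0784,15
7.375,0.136,0.0747,15
7.625,0.1231,0.0711,15
7.875,0.1131,0.0678,15
8.125,0.1053,0.0648,15
8.375,0.0993,0.062,15
8.625,0.0947,0.0597,15
8.875,0.0912,0.0577,15
9.125,0.0885,0.056,15
9.375,0.0865,0.0546,15
9.625,0.0849,0.0534,15
9.875,0.0837,0.0526,15
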