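buffer_km,split,cv_rmse,cv_r2,cv_mae,test_rmse,test_r2,test_mae
0,70:30,70,0.49,17.29,84.17,0.48,20.93
0,80:20,65.3,0.59,16.74,87.21,0.29,19.29
0,90:10,68.96,0.63,17.08,50.29,0.21,14
2,70:30,52.22,0.51,13.4,62.96,0.7,12.35
2,80:20,61.09,0.51,14.46,22.98,0.59,8.65
2,90:10,57.13,0.54,13.13,20.33,0.68,8.38
5,70:30,49.55,0.6,11.26,30.2,0.33,7.09
5,80:20,45.63,0.62,9.9,35.77,0.25,7.9
5,90:10,44.07,0.6,9.3,35.67,0.38,7.22
10,70:30,21.11,0.62,5.84,11.13,0.79,4.74
10,80:20,19.45,0.67,5.4,12.68,0.73,4.94
10,90:10,17.53,0.76,4.87,11.75,0.82,4.74
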