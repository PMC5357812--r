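month,total_mean,total_se,male_mean,male_se,female_mean,female_se,avg_temp_c,total_rain_mm
Jan,256.0,11.29,292.2,18.99,227.5,13.16,25.3,7.0
Feb,218.0,9.71,200.9,12.97,232.3,14.08,22.7,13.2
Mar,248.2,9.10,240.7,12.40,255.6,13.31,22.2,28.4
Apr,256.5,9.59,291.7,6.00,260.1,16.05,16.8,0.0
May,218.2,8.15,208.5,10.14,227.8,12.74,16.6,1.2
Jun,162.1,4.84,175.4,7.08,148.9,6.44,11.5,15.2
Jul,157.6,4.09,165.1,6.23,150.0,5.24,10.6,20.4
Aug,191.1,6.46,212.2,10.30,170.5,7.54,14.7,25.0
Sep,302.0,14.68,371.1,26.15,233.0,10.80,15.1,8.8
Oct,471.7,20.57,624.1,29.74,319.3,22.64,20.7,17.8
Nov,296.6,14.66,390.1,24.41,207.2,13.21,19.9,10.2
Dec,306.7,14.31,349.8,23.02,275.4,17.89,23.3,23.8
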