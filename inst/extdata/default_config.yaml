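start_date: '2023-09-01'
n_collars: 18
n_plots: 3
sample_day: 10
stands:
  CA:
    stand_id: CA
    a_true: 0.13200000000000001
    b_true: 0.10100000000000001
    c_true: 0.094
    calib_slope: 0.85257548845470643
    calib_intercept: 3.1384547069271882
    rs_noise_cv: 0.25
    temp_noise_sd: 0.29999999999999999
    moist_noise_sd: 1.0
    air_noise_sd: 1.19999999999999996
    collar_sd: 0.10000000000000001
    moist_dry_mean: 5.58999999999999986
    moist_wet_mean: 7.54999999999999982
    air_temp_dry: 22.85000000000000142
    air_temp_wet: 27.64999999999999858
    precip_dry: 39.64999999999999858
    precip_wet: 244.65000000000000568
    rh_dry: 80.48000000000000398
    rh_wet: 82.95000000000000284
    chemistry:
      dry:
        ph:
        - 5.65000000000000036
        - 0.16
        som:
        - 6.59999999999999964
        - 0.65000000000000002
        soc:
        - 3.83000000000000007
        - 0.38
        tn:
        - 0.37
        - 0.04
        tp:
        - 0.08
        - 0.01
        an:
        - 3.97999999999999998
        - 0.22
        ap:
        - 5.25999999999999979
        - 0.04
      wet:
        ph:
        - 4.19000000000000039
        - 0.03
        som:
        - 7.23000000000000043
        - 0.22
        soc:
        - 4.19000000000000039
        - 0.13
        tn:
        - 0.27000000000000002
        - 0.03
        tp:
        - 0.10000000000000001
        - 0.02
        an:
        - 6.09999999999999964
        - 0.26000000000000001
        ap:
        - 1.3600000000000001
        - 0.04
  CO:
    stand_id: CO
    a_true: 0.307
    b_true: 0.066
    c_true: 0.11799999999999999
    calib_slope: 0.61690140845070462
    calib_intercept: 8.52002816901407556
    rs_noise_cv: 0.25
    temp_noise_sd: 0.29999999999999999
    moist_noise_sd: 1.0
    air_noise_sd: 1.19999999999999996
    collar_sd: 0.10000000000000001
    moist_dry_mean: 10.50999999999999979
    moist_wet_mean: 15.22000000000000064
    air_temp_dry: 22.89999999999999858
    air_temp_wet: 27.28000000000000114
    precip_dry: 28.39000000000000057
    precip_wet: 283.25999999999999091
    rh_dry: 79.78000000000000114
    rh_wet: 81.5
    chemistry:
      dry:
        ph:
        - 5.32000000000000028
        - 0.05
        som:
        - 11.10999999999999943
        - 0.69999999999999996
        soc:
        - 6.44000000000000039
        - 0.40000000000000002
        tn:
        - 0.68000000000000005
        - 0.07000000000000001
        tp:
        - 0.51000000000000001
        - 0.06
        an:
        - 9.33000000000000007
        - 0.39000000000000001
        ap:
        - 67.85999999999999943
        - 2.83999999999999986
      wet:
        ph:
        - 5.16000000000000014
        - 0.04
        som:
        - 9.09999999999999964
        - 0.60999999999999999
        soc:
        - 5.28000000000000025
        - 0.08
        tn:
        - 0.48999999999999999
        - 0.04
        tp:
        - 0.58999999999999997
        - 0.07000000000000001
        an:
        - 4.20000000000000018
        - 0.06
        ap:
        - 67.96999999999999886
        - 2.25999999999999979
  MF:
    stand_id: MF
    a_true: 0.128
    b_true: 0.092
    c_true: 0.19900000000000001
    calib_slope: 0.71656050955414008
    calib_intercept: 5.85200636942675345
    rs_noise_cv: 0.25
    temp_noise_sd: 0.29999999999999999
    moist_noise_sd: 1.0
    air_noise_sd: 1.19999999999999996
    collar_sd: 0.10000000000000001
    moist_dry_mean: 6.11000000000000032
    moist_wet_mean: 7.04000000000000004
    air_temp_dry: 22.76999999999999957
    air_temp_wet: 27.26999999999999957
    precip_dry: 35.53000000000000114
    precip_wet: 255.08000000000001251
    rh_dry: 80.73000000000000398
    rh_wet: 83.43000000000000682
    chemistry:
      dry:
        ph:
        - 4.91999999999999993
        - 0.04
        som:
        - 9.82000000000000028
        - 0.5
        soc:
        - 5.70000000000000018
        - 0.28999999999999998
        tn:
        - 0.46999999999999997
        - 0.04
        tp:
        - 0.25
        - 0.03
        an:
        - 4.04000000000000004
        - 0.10000000000000001
        ap:
        - 21.48999999999999844
        - 1.04000000000000004
      wet:
        ph:
        - 4.55999999999999961
        - 0.04
        som:
        - 9.9399999999999995
        - 0.40000000000000002
        soc:
        - 5.76999999999999957
        - 0.07000000000000001
        tn:
        - 0.41999999999999998
        - 0.02
        tp:
        - 0.25
        - 0.04
        an:
        - 6.54999999999999982
        - 0.14000000000000001
        ap:
        - 26.62000000000000099
        - 0.70999999999999996
  SF:
    stand_id: SF
    a_true: 0.28999999999999998
    b_true: 0.10199999999999999
    c_true: 0.052
    calib_slope: 0.896484375
    calib_intercept: 3.27453125000000611
    rs_noise_cv: 0.25
    temp_noise_sd: 0.29999999999999999
    moist_noise_sd: 1.0
    air_noise_sd: 1.19999999999999996
    collar_sd: 0.10000000000000001
    moist_dry_mean: 22.0
    moist_wet_mean: 27.17999999999999972
    air_temp_dry: 22.28000000000000114
    air_temp_wet: 26.87000000000000099
    precip_dry: 28.82999999999999829
    precip_wet: 254.56000000000000227
    rh_dry: 82.46999999999999886
    rh_wet: 85.31999999999999318
    chemistry:
      dry:
        ph:
        - 5.26999999999999957
        - 0.11
        som:
        - 39.75999999999999801
        - 1.43999999999999995
        soc:
        - 23.05999999999999872
        - 0.83999999999999997
        tn:
        - 2.41000000000000014
        - 0.08
        tp:
        - 0.91000000000000003
        - 0.12
        an:
        - 33.52000000000000313
        - 0.58999999999999997
        ap:
        - 9.80000000000000071
        - 0.94999999999999996
      wet:
        ph:
        - 5.42999999999999972
        - 0.03
        som:
        - 34.20000000000000284
        - 0.54000000000000004
        soc:
        - 19.83999999999999986
        - 0.31
        tn:
        - 1.96999999999999997
        - 0.07000000000000001
        tp:
        - 0.85999999999999999
        - 0.16
        an:
        - 10.98000000000000043
        - 0.22
        ap:
        - 4.04999999999999982
        - 0.08
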