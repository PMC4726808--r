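table_id,study,column,reported,self_consistent,note
T8,Shafir and Tversky (1992),expected_theta,2.8151,NA,best-fit reference only
T8,Shafir and Tversky (1992),computed_theta,2.8057,TRUE,
T8,Shafir and Tversky (1992),observed,0.6300,TRUE,
T8,Shafir and Tversky (1992),predicted,0.6408,TRUE,
T8,Shafir and Tversky (1992),fit_error_pct,1.71,TRUE,
T8,Li and Taplin (2002),expected_theta,3.3033,NA,best-fit reference only
T8,Li and Taplin (2002),computed_theta,3.0121,FALSE,inconsistent with the 2.9888 printed for the same averaged conditions elsewhere; recomputation gives 2.9888
T8,Li and Taplin (2002),observed,0.7200,TRUE,
T8,Li and Taplin (2002),predicted,0.7122,TRUE,
T8,Li and Taplin (2002),fit_error_pct,1.09,TRUE,
T8,Busemeyer et al. (2006),expected_theta,2.9738,NA,best-fit reference only
T8,Busemeyer et al. (2006),computed_theta,3.3628,FALSE,printed theta does not reproduce the printed prediction; recomputation gives 2.8286 which does
T8,Busemeyer et al. (2006),observed,0.6600,TRUE,
T8,Busemeyer et al. (2006),predicted,0.7995,TRUE,
T8,Busemeyer et al. (2006),fit_error_pct,21.13,TRUE,
T8,Hristova and Grinberg (2008),expected_theta,2.8255,NA,best-fit reference only
T8,Hristova and Grinberg (2008),computed_theta,2.7400,TRUE,
T8,Hristova and Grinberg (2008),observed,0.8800,TRUE,
T8,Hristova and Grinberg (2008),predicted,0.8968,FALSE,inconsistent with its own printed theta 2.7400 which yields about 0.9065; the printed fit error matches 0.9065
T8,Hristova and Grinberg (2008),fit_error_pct,3.01,TRUE,
T8,Average,expected_theta,2.8718,NA,best-fit reference only
T8,Average,computed_theta,2.7393,TRUE,
T8,Average,observed,0.6400,TRUE,
T8,Average,predicted,0.7208,TRUE,
T8,Average,fit_error_pct,12.63,TRUE,
T11,Game 1,expected_theta,3.0170,NA,best-fit reference only
T11,Game 1,computed_theta,2.9845,TRUE,
T11,Game 1,observed,0.6000,TRUE,
T11,Game 1,predicted,0.6313,TRUE,
T11,Game 1,fit_error_pct,5.21,TRUE,
T11,Game 2,expected_theta,3.0758,NA,best-fit reference only
T11,Game 2,computed_theta,3.0436,TRUE,
T11,Game 2,observed,0.6300,TRUE,
T11,Game 2,predicted,0.7011,TRUE,
T11,Game 2,fit_error_pct,11.28,TRUE,
T11,Game 3,expected_theta,2.8052,NA,best-fit reference only
T11,Game 3,computed_theta,2.9810,TRUE,
T11,Game 3,observed,0.8667,TRUE,
T11,Game 3,predicted,0.8113,TRUE,
T11,Game 3,fit_error_pct,6.39,TRUE,
T11,Game 4,expected_theta,3.2313,NA,best-fit reference only
T11,Game 4,computed_theta,3.0306,TRUE,
T11,Game 4,observed,0.7000,TRUE,
T11,Game 4,predicted,0.7341,TRUE,
T11,Game 4,fit_error_pct,4.87,TRUE,
T11,Game 5,expected_theta,2.8519,NA,best-fit reference only
T11,Game 5,computed_theta,2.8511,TRUE,
T11,Game 5,observed,0.7000,TRUE,
T11,Game 5,predicted,0.7006,TRUE,
T11,Game 5,fit_error_pct,0.08,TRUE,
T11,Game 6,expected_theta,1.5708,NA,best-fit reference only
T11,Game 6,computed_theta,2.9350,TRUE,
T11,Game 6,observed,0.8000,TRUE,
T11,Game 6,predicted,0.7169,TRUE,
T11,Game 6,fit_error_pct,10.39,TRUE,
T11,Game 7,expected_theta,3.7812,NA,best-fit reference only
T11,Game 7,computed_theta,2.7365,TRUE,
T11,Game 7,observed,0.7667,TRUE,
T11,Game 7,predicted,0.7159,TRUE,
T11,Game 7,fit_error_pct,6.63,TRUE,
T11,Average,expected_theta,3.3033,NA,best-fit reference only
T11,Average,computed_theta,2.9888,TRUE,
T11,Average,observed,0.7200,TRUE,
T11,Average,predicted,0.7122,TRUE,
T11,Average,fit_error_pct,1.09,TRUE,
T12,Shafir and Tversky (1992),observed,0.6300,TRUE,
T12,Shafir and Tversky (1992),qpdt,0.6550,TRUE,
T12,Shafir and Tversky (1992),qpdt_fit,0.0397,TRUE,
T12,Shafir and Tversky (1992),qlbn,0.6408,TRUE,
T12,Shafir and Tversky (1992),qlbn_fit,0.0171,TRUE,
T12,Li and Taplin (2002),observed,0.7200,TRUE,
T12,Li and Taplin (2002),qpdt,0.5450,TRUE,
T12,Li and Taplin (2002),qpdt_fit,0.2431,TRUE,
T12,Li and Taplin (2002),qlbn,0.7122,TRUE,
T12,Li and Taplin (2002),qlbn_fit,0.0108,TRUE,
T12,Busemeyer et al. (2006),observed,0.6600,TRUE,
T12,Busemeyer et al. (2006),qpdt,0.6250,TRUE,
T12,Busemeyer et al. (2006),qpdt_fit,0.0531,TRUE,
T12,Busemeyer et al. (2006),qlbn,0.7995,TRUE,
T12,Busemeyer et al. (2006),qlbn_fit,0.2113,TRUE,
T12,Hristova and Grinberg (2008),observed,0.8800,TRUE,
T12,Hristova and Grinberg (2008),qpdt,0.7000,TRUE,
T12,Hristova and Grinberg (2008),qpdt_fit,0.2045,TRUE,
T12,Hristova and Grinberg (2008),qlbn,0.8968,FALSE,inconsistent with the heuristic chain for these conditions (recomputation gives about 0.9065)
T12,Hristova and Grinberg (2008),qlbn_fit,0.0191,FALSE,follows from the inconsistent 0.8968
T12,Tversky and Shafir (1992),observed,0.3700,TRUE,
T12,Tversky and Shafir (1992),qpdt,0.3850,TRUE,
T12,Tversky and Shafir (1992),qpdt_fit,0.0405,TRUE,
T12,Tversky and Shafir (1992),qlbn,0.3641,TRUE,
T12,Tversky and Shafir (1992),qlbn_fit,0.0159,TRUE,
T12,Kuhberger et al. (2001),observed,0.4800,TRUE,
T12,Kuhberger et al. (2001),qpdt,0.3450,TRUE,
T12,Kuhberger et al. (2001),qpdt_fit,0.2813,TRUE,
T12,Kuhberger et al. (2001),qlbn,0.4018,TRUE,
T12,Kuhberger et al. (2001),qlbn_fit,0.1629,TRUE,
T12,Lambdin and Burdsal (2007),observed,0.4100,TRUE,
T12,Lambdin and Burdsal (2007),qpdt,0.2900,TRUE,
T12,Lambdin and Burdsal (2007),qpdt_fit,0.2927,TRUE,
T12,Lambdin and Burdsal (2007),qlbn,0.4085,FALSE,below the 0.4593 minimum attainable over the phase parameter for these conditions
T12,Lambdin and Burdsal (2007),qlbn_fit,0.0037,FALSE,follows from the inconsistent 0.4085
T12,Average fit error,qpdt_fit,0.1651,TRUE,
T12,Average fit error,qlbn_fit,0.0630,FALSE,includes the inconsistent Lambdin and Hristova rows; reference only
T13,Game 1,observed,0.6000,TRUE,
T13,Game 1,qpdt,0.4502,TRUE,
T13,Game 1,qpdt_fit,0.2497,TRUE,
T13,Game 1,qlbn,0.6313,TRUE,
T13,Game 1,qlbn_fit,0.0522,TRUE,
T13,Game 2,observed,0.6300,TRUE,
T13,Game 2,qpdt,0.5333,TRUE,
T13,Game 2,qpdt_fit,0.1535,TRUE,
T13,Game 2,qlbn,0.7011,TRUE,
T13,Game 2,qlbn_fit,0.1129,TRUE,
T13,Game 3,observed,0.8667,TRUE,
T13,Game 3,qpdt,0.6334,TRUE,
T13,Game 3,qpdt_fit,0.2692,TRUE,
T13,Game 3,qlbn,0.8113,TRUE,
T13,Game 3,qlbn_fit,0.0639,TRUE,
T13,Game 4,observed,0.7000,TRUE,
T13,Game 4,qpdt,0.5667,TRUE,
T13,Game 4,qpdt_fit,0.1904,TRUE,
T13,Game 4,qlbn,0.7341,TRUE,
T13,Game 4,qlbn_fit,0.0487,TRUE,
T13,Game 5,observed,0.7000,TRUE,
T13,Game 5,qpdt,0.5333,TRUE,
T13,Game 5,qpdt_fit,0.2381,TRUE,
T13,Game 5,qlbn,0.7006,TRUE,
T13,Game 5,qlbn_fit,0.0009,TRUE,
T13,Game 6,observed,0.8000,TRUE,
T13,Game 6,qpdt,0.5500,TRUE,
T13,Game 6,qpdt_fit,0.3125,TRUE,
T13,Game 6,qlbn,0.7169,TRUE,
T13,Game 6,qlbn_fit,0.1039,TRUE,
T13,Game 7,observed,0.7667,TRUE,
T13,Game 7,qpdt,0.5500,TRUE,
T13,Game 7,qpdt_fit,0.2826,TRUE,
T13,Game 7,qlbn,0.7159,TRUE,
T13,Game 7,qlbn_fit,0.0663,TRUE,
T13,Average fit error,qpdt_fit,0.2423,TRUE,
T13,Average fit error,qlbn_fit,0.0641,TRUE,
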