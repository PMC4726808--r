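table_id,study,game,p_known_1,p_known_2,p_unknown_observed,prior1,note
T1,Shafir and Tversky (1992),prisoners_dilemma,0.97,0.84,0.63,0.5,
T1,Croson (1999),prisoners_dilemma,0.67,0.32,0.30,0.5,average of the first two payoff matrices
T1,Li and Taplin (2002),prisoners_dilemma,0.82,0.77,0.72,0.5,average of seven experiments
T1,Busemeyer et al. (2006),prisoners_dilemma,0.91,0.84,0.66,0.5,
T1,Hristova and Grinberg (2008),prisoners_dilemma,0.97,0.93,0.88,0.5,
T1,Average,prisoners_dilemma,0.87,0.74,0.64,0.5,
T2,Tversky and Shafir (1992),two_stage_gamble,0.69,0.58,0.37,0.5,
T2,Kuhberger et al. (2001),two_stage_gamble,0.72,0.47,0.48,0.5,
T2,Lambdin and Burdsal (2007),two_stage_gamble,0.63,0.45,0.41,0.5,
T2,Average,two_stage_gamble,0.68,0.50,0.42,0.5,
T9,Game 1,prisoners_dilemma,0.17,0.68,0.225,0.5,guessed rather than known condition
T9,Game 2,prisoners_dilemma,0.47,0.65,0.375,0.5,guessed rather than known condition
T9,Average,prisoners_dilemma,0.67,0.32,0.30,0.5,printed column order of the source Average row matches the pooled literature table rather than the Game rows; stored in pooled-table order
T10,Game 1,prisoners_dilemma,0.7333,0.6670,0.6000,0.5,
T10,Game 2,prisoners_dilemma,0.8000,0.7667,0.6300,0.5,
T10,Game 3,prisoners_dilemma,0.9000,0.8667,0.8667,0.5,
T10,Game 4,prisoners_dilemma,0.8333,0.8000,0.7000,0.5,
T10,Game 5,prisoners_dilemma,0.8333,0.7333,0.7000,0.5,
T10,Game 6,prisoners_dilemma,0.7667,0.8333,0.8000,0.5,
T10,Game 7,prisoners_dilemma,0.8667,0.7333,0.7667,0.5,
T10,Average,prisoners_dilemma,0.8200,0.7700,0.7200,0.5,
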