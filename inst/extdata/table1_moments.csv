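item,hoa_mean,hoa_sd,apos_mean,apos_sd,aneg_mean,aneg_sd
age,68.86,4.60,76.85,7.30,76.07,5.41
education,13.33,4.23,6.92,4.42,6.37,4.36
gds,8.71,4.22,13.12,6.78,15.70,6.37
mmse,28.95,0.92,20.88,3.86,22.74,4.85
word_list_learning,21.86,3.18,9.96,3.40,11.63,4.10
word_list_learning_z,1.31,0.76,-1.36,0.65,-0.98,0.83
word_list_recall,7.76,1.45,1.38,1.42,2.63,2.06
word_list_recall_z,0.93,0.74,2.05,0.64,-1.42,0.88
word_list_recognition,9.57,0.81,5.58,3.00,6.22,2.99
word_list_recognition_z,0.39,0.59,-1.88,1.97,-1.43,1.72
constructional_praxis,10.14,0.96,8.58,2.37,7.96,1.83
constructional_praxis_z,-0.06,0.72,0.04,0.88,-0.53,1.48
constructional_praxis_recall,7.43,2.42,1.58,1.98,2.81,2.20
constructional_praxis_recall_z,0.086,0.84,-1.48,0.93,-0.64,0.95
trail_making_a,1.00,0,0.85,0.37,0.78,0.42
trail_making_a_z,1.38,0.63,-0.01,0.99,-0.66,1.46
trail_making_a_seconds,40.48,12.90,113.14,58.22,138.14,86.32
boston_naming,12.76,1.58,9.23,3.01,8.70,2.84
boston_naming_z,0.75,0.61,-0.08,0.95,-0.17,0.84
digit_span_forward,6.52,1.25,4.46,0.90,4.00,0.83
digit_span_backward,4.47,1.17,2.73,0.67,2.63,0.88
cowat_animal,16.71,4.28,8.77,2.75,9.56,3.33
cowat_animal_z,0.06,0.86,-1.27,0.67,-1.09,0.89
cowat_market,20.57,6.66,10.88,4.26,10.59,4.26
cowat_market_z,0.38,1.20,-0.65,0.77,-0.67,0.93
cowat_k,9.38,3.61,4.65,3.23,2.67,2.82
cowat_o,10.24,4.09,4.35,3.20,2.79,2.87
cowat_s,10.19,4.34,5.17,3.70,3.17,3.09
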