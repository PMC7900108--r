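item,f_three_group,t_hoa_apos,t_hoa_aneg,t_apos_aneg
age,12.356,-4.359,-4.892,0.439
education,17.940,5.037,5.557,0.458
gds,8.060,-2.594,-4.339,-1.434
mmse,28.682,9.345,5.777,-1.538
word_list_learning,71.624,12.268,9.432,-1.610
word_list_learning_z,83.036,12.958,9.805,-1.843
word_list_recall,90.673,15.205,9.700,2.555
word_list_recall_z,95.745,14.783,9.819,2.958
word_list_recognition,15.677,5.926,4.980,-0.785
word_list_recognition_z,12.829,5.088,4.632,-0.896
constructional_praxis,8.385,2.840,4.946,1.058
constructional_praxis_z,1.976,-0.454,1.315,1.698
constructional_praxis_recall,44.722,9.114,6.896,2.148
constructional_praxis_recall_z,17.236,5.970,2.774,-3.236
trail_making_a,2.634,1.912,2.398,-0.626
trail_making_a_z,19.426,5.458,5.858,1.695
trail_making_a_seconds,14.784,-5.587,-5.128,-1.118
boston_naming,16.128,4.856,5.873,0.656
boston_naming_z,8.649,3.469,4.265,0.395
digit_span_forward,41.870,6.558,8.384,1.934
digit_span_backward,29.478,6.444,6.243,0.469
cowat_animal,36.372,7.712,6.521,-0.935
cowat_animal_z,17.875,5.952,4.503,-0.835
cowat_market,28.523,6.051,6.308,0.250
cowat_market_z,8.872,3.583,3.446,0.089
cowat_k,25.332,4.586,6.991,2.247
cowat_o,29.380,5.349,7.140,1.756
cowat_s,20.889,4.135,6.311,2.022
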