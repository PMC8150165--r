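{"n_per_class":{"control":106,"F0":13,"F1":13,"F2":13,"F3":41,"F4":41,"alcohol_cirrhosis":48},"panel":["androsterone","etiocholanolone","dehydroepiandrosterone","16a_hydroxy_dhea","androstenedione","11b_hydroxyandrosterone","11b_hydroxyetiocholanolone","11_oxoetiocholanolone","pregnanediol","pregnenediol","pregnanetriol","pregnenetriol","pregnanetriolone","tetrahydrocortisol","5a_tetrahydrocortisol","tetrahydrocortisone","cortisol","cortisone","6b_hydroxycortisol","a_cortol","b_cortol","a_cortolone","b_cortolone","tetrahydrocorticosterone","5a_tetrahydrocorticosterone","tetrahydro_11_dehydrocorticosterone","5a_tetrahydro_11_dehydrocorticosterone","tetrahydro_11_deoxycorticosterone","tetrahydrodeoxycortisol","tetrahydroaldosterone","5a_dihydrotestosterone","testosterone"],"informative_features":{"F0-2_vs_F3-4":{"classes":["F3","F4"],"effects":{"etiocholanolone":1.1000000000000001,"dehydroepiandrosterone":1.0333333333333334,"5a_tetrahydro_11_dehydrocorticosterone":0.96666666666666679,"androstenedione":0.90000000000000002,"5a_tetrahydrocorticosterone":0.83333333333333337,"pregnenetriol":0.76666666666666672,"tetrahydro_11_deoxycorticosterone":0.69999999999999996,"tetrahydroaldosterone":0.6333333333333333,"cortisone":0.56666666666666665,"11_oxoetiocholanolone":0.5}},"F0-3_vs_F4":{"classes":"F4","effects":{"etiocholanolone":0.5,"tetrahydrocorticosterone":0.46111111111111114,"5a_tetrahydro_11_dehydrocorticosterone":0.42222222222222222,"tetrahydro_11_deoxycorticosterone":0.3833333333333333,"dehydroepiandrosterone":0.34444444444444444,"androsterone":0.30555555555555558,"tetrahydrocortisone":0.26666666666666666,"tetrahydrocortisol":0.22777777777777775,"pregnenetriol":0.18888888888888888,"5a_tetrahydrocorticosterone":0.14999999999999999}},"control_vs_F3-4":{"classes":"control","effects":{"5a_tetrahydro_11_dehydrocorticosterone":-0.5,"11_oxoetiocholanolone":-0.46111111111111114,"etiocholanolone":-0.42222222222222222,"cortisone":-0.3833333333333333,"pregnenediol":-0.34444444444444444,"pregnanetriol":-0.30555555555555558,"tetrahydro_11_deoxycorticosterone":-0.26666666666666666,"11b_hydroxyetiocholanolone":-0.22777777777777775,"pregnanediol":-0.18888888888888888,"5a_tetrahydrocorticosterone":-0.14999999999999999}},"control_vs_F4":{"classes":"control","effects":{"5a_tetrahydro_11_dehydrocorticosterone":-0.29999999999999999,"11_oxoetiocholanolone":-0.27777777777777779,"etiocholanolone":-0.25555555555555554,"cortisone":-0.23333333333333334,"tetrahydro_11_deoxycorticosterone":-0.21111111111111111,"pregnenediol":-0.18888888888888888,"pregnanetriol":-0.16666666666666669,"tetrahydrocorticosterone":-0.14444444444444446,"pregnanediol":-0.12222222222222223,"5a_tetrahydrocorticosterone":-0.10000000000000001}},"control_vs_F0-4":{"classes":["F0","F1","F2","F3","F4"],"effects":{"androsterone":0.40000000000000002,"a_cortolone":0.40000000000000002,"b_cortolone":0.29999999999999999,"pregnanediol":0.29999999999999999}},"enzyme_shift_F3-4":{"classes":["F3","F4"],"effects":{"5a_tetrahydrocortisol":0.59999999999999998,"tetrahydrocortisone":-0.40000000000000002}},"F4_vs_alcohol_cirrhosis":{"classes":"alcohol_cirrhosis","effects":{"androsterone":-1,"etiocholanolone":-0.80000000000000004,"dehydroepiandrosterone":-0.80000000000000004,"11b_hydroxyandrosterone":0.59999999999999998,"tetrahydrocortisol":0.5}}},"class_params":{"control":{"age":[55.5,11.1],"bmi":[30.699999999999999,5.7999999999999998],"t2d":0.037999999999999999,"ast":[22,8],"alt":[13.199999999999999,8.6999999999999993],"platelets":[250,60],"albumin":[4.5,0.29999999999999999],"hba1c":[38.600000000000001,10.4]},"F0":{"age":[45.600000000000001,12],"bmi":[38.5,7],"t2d":0.308,"ast":[34.399999999999999,22],"alt":[63.399999999999999,51.399999999999999],"platelets":[242.5,64.200000000000003],"albumin":[4.4000000000000004,0.40000000000000002],"hba1c":[40.799999999999997,8.1999999999999993]},"F1":{"age":[45.600000000000001,12],"bmi":[38.5,7],"t2d":0.308,"ast":[34.399999999999999,22],"alt":[63.399999999999999,51.399999999999999],"platelets":[242.5,64.200000000000003],"albumin":[4.4000000000000004,0.40000000000000002],"hba1c":[40.799999999999997,8.1999999999999993]},"F2":{"age":[45.600000000000001,12],"bmi":[38.5,7],"t2d":0.308,"ast":[34.399999999999999,22],"alt":[63.399999999999999,51.399999999999999],"platelets":[242.5,64.200000000000003],"albumin":[4.4000000000000004,0.40000000000000002],"hba1c":[40.799999999999997,8.1999999999999993]},"F3":{"age":[61.799999999999997,10.800000000000001],"bmi":[33.700000000000003,5.7999999999999998],"t2d":0.63400000000000001,"ast":[49.100000000000001,31.800000000000001],"alt":[49.899999999999999,36.899999999999999],"platelets":[183.90000000000001,67],"albumin":[4.0999999999999996,0.5],"hba1c":[50,13.5]},"F4":{"age":[61.799999999999997,10.800000000000001],"bmi":[33.700000000000003,5.7999999999999998],"t2d":0.63400000000000001,"ast":[49.100000000000001,31.800000000000001],"alt":[49.899999999999999,36.899999999999999],"platelets":[183.90000000000001,67],"albumin":[4.0999999999999996,0.5],"hba1c":[50,13.5]},"alcohol_cirrhosis":{"age":[58,11],"bmi":[29,5],"t2d":0.25,"ast":[70,35],"alt":[40,25],"platelets":[150,60],"albumin":[3.6000000000000001,0.59999999999999998],"hba1c":[40,10]}},"baseline_log10":{"androsterone":3,"etiocholanolone":3,"dehydroepiandrosterone":2,"16a_hydroxy_dhea":2.2999999999999998,"androstenedione":1.5,"11b_hydroxyandrosterone":2.6000000000000001,"11b_hydroxyetiocholanolone":2.2999999999999998,"11_oxoetiocholanolone":2.5,"pregnanediol":2.7000000000000002,"pregnenediol":2.2999999999999998,"pregnanetriol":2.7999999999999998,"pregnenetriol":2.1000000000000001,"pregnanetriolone":1.5,"tetrahydrocortisol":3.2000000000000002,"5a_tetrahydrocortisol":3.2000000000000002,"tetrahydrocortisone":3.5,"cortisol":1.8999999999999999,"cortisone":2,"6b_hydroxycortisol":1.5,"a_cortol":2.5,"b_cortol":2.3999999999999999,"a_cortolone":2.7999999999999998,"b_cortolone":2.6000000000000001,"tetrahydrocorticosterone":2.2999999999999998,"5a_tetrahydrocorticosterone":2.3999999999999999,"tetrahydro_11_dehydrocorticosterone":2.2000000000000002,"5a_tetrahydro_11_dehydrocorticosterone":2.1000000000000001,"tetrahydro_11_deoxycorticosterone":1.6000000000000001,"tetrahydrodeoxycortisol":1.3,"tetrahydroaldosterone":1.6000000000000001,"5a_dihydrotestosterone":0.29999999999999999,"testosterone":0.69999999999999996},"creatinine_lognormal":{"meanlog":4.6051701859880918,"sdlog":0.5},"noise_sd":0.25,"detection_floor":1,"seed":1}
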