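panel,outcome,predictor,a,b,c,cohort_n,cases,nnh,rr,specificity,sensitivity,npv,ppv,ess
Ai,new_ed,prostate_disease,403,4792,296,15634,699,20.3,2.7,67.9,57.7,97.2,7.8,25.6
Ai,new_ed,encounters_gt_27.5,506,7312,193,15634,699,25.0,2.6,51.0,72.4,97.5,6.5,23.4
Ai,new_ed,encounters_after_exposure_gt_12.5,534,8129,165,15634,699,26.3,2.6,45.6,76.4,97.6,6.2,22.0
Ai,new_ed,prostate_surgery,203,1300,496,15634,699,10.0,3.8,91.3,29.0,96.5,13.5,20.3
Ai,new_ed,exposure_days_gt_90.5,497,7685,202,15634,699,29.7,2.2,48.5,71.1,97.3,6.1,19.6
Ai,new_ed,encounters_before_exposure_gt_8.5,426,6174,273,15634,699,29.1,2.1,58.7,60.9,97.0,6.5,19.6
Ai,new_ed,nsaid,489,7953,210,15634,699,34.8,2.0,46.7,70.0,97.1,5.8,16.7
Ai,new_ed,age_le_72.6,608,10544,91,15634,699,29.2,2.7,29.4,87.0,98.0,5.5,16.4
Ai,new_ed,hypertension,371,5507,328,15634,699,33.9,1.9,63.1,53.1,96.6,6.3,16.2
Ai,new_ed,depression,162,1591,537,15634,699,18.6,2.4,89.3,23.2,96.1,9.2,12.5
Ai,new_ed,progress_notes_gt_8.5,343,5470,356,15634,699,43.9,1.6,63.4,49.1,96.4,5.9,12.4
Ai,new_ed,high_dose_finasteride,393,6557,306,15634,699,46.9,1.6,56.1,56.2,96.5,5.7,12.3
Ai,new_ed,progress_notes_after_exposure_gt_2.5,473,8346,226,15634,699,48.8,1.6,44.1,67.7,96.7,5.4,11.8
Ai,new_ed,smoking,284,4561,415,15634,699,49.6,1.5,69.5,40.6,96.2,5.9,10.1
Ai,new_ed,prostate_cancer,108,816,591,15634,699,13.0,2.9,94.5,15.5,96.0,11.7,10.0
Ai,new_ed,androgen,64,229,635,15634,699,5.6,5.3,98.5,9.2,95.9,21.8,7.6
Ai,new_ed,obesity,104,1140,595,15634,699,23.7,2.0,92.4,14.9,95.9,8.4,7.2
Ai,new_ed,vascular_disease,260,4500,439,15634,699,70.2,1.4,69.9,37.2,96.0,5.5,7.1
Ai,new_ed,ssri,147,2106,552,15634,699,41.7,1.6,85.9,21.0,95.9,6.5,6.9
Ai,new_ed,cyclovir,100,1140,599,15634,699,25.6,1.9,92.4,14.3,95.8,8.1,6.7
Ai,new_ed,diuretic,210,3818,489,15634,699,100.0,1.2,74.4,30.0,95.8,5.2,4.5
Ai,new_ed,dutasteride,137,2333,562,15634,699,78.3,1.3,84.4,19.6,95.7,5.5,4.0
Ai,new_ed,hsv,47,412,652,15634,699,16.8,2.4,97.2,6.7,95.7,10.2,4.0
Ai,new_ed,diabetes,113,1852,586,15634,699,68.3,1.3,87.6,16.2,95.7,5.8,3.8
Ai,new_ed,antiandrogen,22,208,677,15634,699,19.3,2.2,98.6,3.1,95.6,9.6,1.8
Ai,new_ed,peyronie,10,55,689,15634,699,9.1,3.5,99.6,1.4,95.6,15.4,1.1
Ai,new_ed,hiv,13,145,686,15634,699,26.3,1.9,99.0,1.9,95.6,8.2,0.9
Aii,new_low_libido,exposure_days_gt_96.5,161,8006,49,15634,210,76.0,3.0,48.1,76.7,99.3,2.0,24.8
Aii,new_low_libido,age_le_67.4,179,9361,31,15634,210,73.1,3.7,39.3,85.2,99.5,1.9,24.6
Aii,new_low_libido,encounters_after_exposure_gt_9.5,170,9532,40,15634,210,92.8,2.6,38.2,81.0,99.3,1.8,19.1
Aii,new_low_libido,encounters_gt_34.5,133,6871,77,15634,210,99.3,2.1,55.5,63.3,99.1,1.9,18.8
Aii,new_low_libido,ssri,68,2185,142,15634,210,51.1,2.8,85.8,32.4,98.9,3.0,18.2
Aii,new_low_libido,androgen,39,254,171,15634,210,8.2,11.9,98.4,18.6,98.9,13.3,16.9
Aii,new_low_libido,depression,58,1695,152,15634,210,45.2,3.0,89.0,27.6,98.9,3.3,16.6
Aii,new_low_libido,nsaid,139,8303,71,15634,210,151.7,1.7,46.2,66.2,99.0,1.6,12.4
Aii,new_low_libido,encounters_before_exposure_gt_11.5,98,5677,112,15634,210,178.3,1.5,63.2,46.7,98.9,1.7,9.9
Aii,new_low_libido,obesity,34,1210,176,15634,210,66.2,2.2,92.2,16.2,98.8,2.7,8.3
Aii,new_low_libido,cyclovir,33,1207,177,15634,210,69.9,2.2,92.2,15.7,98.8,2.7,7.9
Aii,new_low_libido,hsv,18,441,192,15634,210,37.6,3.1,97.1,8.6,98.7,3.9,5.7
Aii,new_low_libido,alcoholism,15,422,195,15634,210,46.5,2.7,97.3,7.1,98.7,3.4,4.4
Aii,new_low_libido,peyronie,5,60,205,15634,210,15.7,5.8,99.6,2.4,98.7,7.7,2.0
B,new_ped,prostate_surgery,66,120,101,11909,167,2.9,41.2,99.0,39.5,99.1,35.5,38.5
B,new_ped,prostate_disease,103,3950,64,11909,167,57.9,3.1,66.4,61.7,99.2,2.5,28.0
B,new_ped,exposure_days_gt_179.5,113,5555,54,11909,167,88.6,2.3,52.7,67.7,99.1,2.0,20.4
B,new_ped,nsaid,121,6173,46,11909,167,90.6,2.3,47.4,72.5,99.2,1.9,19.9
B,new_ped,hypertension,94,4392,73,11909,167,89.9,2.1,62.6,56.3,99.0,2.1,18.9
B,new_ped,age_le_71.8,148,8212,19,11909,167,81.0,3.3,30.1,88.6,99.5,1.8,18.7
B,new_ped,encounters_before_exposure_gt_2.5,128,6842,39,11909,167,95.5,2.3,41.7,76.6,99.2,1.8,18.4
B,new_ped,age_at_first_exposure_le_70.3,150,8509,17,11909,167,82.7,3.3,27.5,89.8,99.5,1.7,17.4
B,new_ped,encounters_gt_13.5,125,6758,42,11909,167,102.0,2.2,42.4,74.9,99.2,1.8,17.3
B,new_ped,prostate_cancer,37,739,130,11909,167,27.8,4.1,93.7,22.2,98.8,4.8,15.9
B,new_ped,high_dose_5ari,114,6400,53,11909,167,130.3,1.8,45.5,68.3,99.0,1.8,13.8
B,new_ped,high_dose_finasteride,91,5047,76,11909,167,154.2,1.6,57.0,54.5,98.9,1.8,11.5
B,new_ped,encounters_after_exposure_gt_3.5,140,8522,27,11909,167,127.4,1.9,27.4,83.8,99.2,1.6,11.3
B,new_ped,smoking,67,3464,100,11909,167,142.1,1.6,70.5,40.1,98.8,1.9,10.6
B,new_ped,androgen,20,220,147,11909,167,14.1,6.6,98.1,12.0,98.7,8.3,10.1
B,new_ped,depression,34,1239,133,11909,167,70.4,2.1,89.4,20.4,98.7,2.7,9.8
B,new_ped,ssri,39,1618,128,11909,167,90.5,1.9,86.2,23.4,98.8,2.4,9.6
B,new_ped,dutasteride,40,1902,127,11909,167,127.3,1.6,83.8,24.0,98.7,2.1,7.8
B,new_ped,vascular_disease,66,3765,101,11909,167,211.6,1.4,67.9,39.5,98.7,1.7,7.5
B,new_ped,diuretic,55,2998,112,11909,167,186.3,1.4,74.5,32.9,98.7,1.8,7.4
B,new_ped,diabetes,31,1429,136,11909,167,121.7,1.6,87.8,18.6,98.7,2.1,6.4
B,new_ped,cyclovir,20,865,147,11909,167,107.9,1.7,92.6,12.0,98.7,2.3,4.6
B,new_ped,obesity,19,827,148,11909,167,110.1,1.7,93.0,11.4,98.7,2.2,4.3
B,new_ped,alcoholism,10,307,157,11909,167,55.5,2.3,97.4,6.0,98.6,3.2,3.4
B,new_ped,hiv,7,128,160,11909,167,26.1,3.8,98.9,4.2,98.6,5.2,3.1
B,new_ped,antiandrogen,7,168,160,11909,167,37.9,2.9,98.6,4.2,98.6,4.0,2.8
C,young_new_ped,exposure_days_gt_205.0,30,2557,4,4284,34,108.2,4.9,39.8,88.2,99.8,1.2,28.1
C,young_new_ped,cyclovir,12,325,22,4284,34,33.3,6.4,92.4,35.3,99.4,3.6,27.6
C,young_new_ped,ssri,13,478,21,4284,34,47.8,4.8,88.8,38.2,99.4,2.6,27.0
C,young_new_ped,depression,11,329,23,4284,34,37.7,5.5,92.3,32.4,99.4,3.2,24.6
C,young_new_ped,nsaid,16,1181,18,4284,34,132.7,2.3,72.2,47.1,99.4,1.3,19.3
C,young_new_ped,smoking,9,582,25,4284,34,118.2,2.2,86.3,26.5,99.3,1.5,12.8
C,young_new_ped,hypertension,7,340,27,4284,34,75.1,2.9,92.0,20.6,99.3,2.0,12.6
C,young_new_ped,hiv,4,38,30,4284,34,11.3,13.5,99.1,11.8,99.3,9.5,10.9
C,young_new_ped,diabetes,2,39,32,4284,34,24.2,6.5,99.1,5.9,99.2,4.9,5.0
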