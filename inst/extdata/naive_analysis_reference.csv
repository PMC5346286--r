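panel,stratum,effect,a,b,c,exposed_n,unexposed_n,nnh,rr,specificity,sensitivity,npv,ppv,ess
A,all_5ari,ed,1381,16094,14367,17475,673793,17.3,3.706,97.6,8.8,97.9,7.9,6.4
A,all_5ari,pde5i,2346,15129,26823,17475,673793,10.6,3.372,97.7,8.0,96.0,13.4,5.8
A,all_5ari,low_libido,381,17094,5520,17475,673793,73.5,2.661,97.5,6.5,99.2,2.2,4.0
A,high_dose_5ari,ed,915,8448,14367,9363,673793,13.1,4.583,98.7,6.0,97.9,9.8,4.7
A,high_dose_5ari,pde5i,1506,7857,26823,9363,673793,8.3,4.040,98.8,5.3,96.0,16.1,4.1
A,high_dose_5ari,low_libido,182,9181,5520,9363,673793,88.9,2.373,98.6,3.2,99.2,1.9,1.8
A,high_dose_finasteride,ed,628,5919,14367,6547,673793,13.4,4.499,99.1,4.2,97.9,9.6,3.3
A,high_dose_finasteride,pde5i,1027,5520,26823,6547,673793,8.5,3.940,99.2,3.7,96.0,15.7,2.8
A,high_dose_finasteride,low_libido,123,6424,5520,6547,673793,94.4,2.293,99.0,2.2,99.2,1.9,1.2
A,low_dose_finasteride,ed,383,7036,14367,7419,673793,33.0,2.421,98.9,2.6,97.9,5.2,1.5
A,low_dose_finasteride,pde5i,707,6712,26823,7419,673793,18.0,2.394,99.0,2.6,96.0,9.5,1.5
A,low_dose_finasteride,low_libido,175,7244,5520,7419,673793,65.0,2.879,98.9,3.1,99.2,2.4,2.0
A,dutasteride,ed,162,1759,14367,1921,673793,15.9,3.955,99.7,1.1,97.9,8.4,0.9
A,dutasteride,pde5i,280,1641,26823,1921,673793,9.4,3.661,99.7,1.0,96.0,14.6,0.8
A,dutasteride,low_libido,37,1884,5520,1921,673793,90.3,2.351,99.7,0.7,99.2,1.9,0.4
B,young_low_dose_finasteride,ed,222,5360,2447,5582,321112,31.1,5.219,98.3,8.3,99.2,4.0,6.7
B,young_low_dose_finasteride,pde5i,386,5196,3787,5582,321112,17.4,5.864,98.4,9.2,98.8,6.9,7.6
B,young_low_dose_finasteride,low_libido,133,5449,1359,5582,321112,51.0,5.630,98.3,8.9,99.6,2.4,7.2
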