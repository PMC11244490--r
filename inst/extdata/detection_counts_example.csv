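plot,source,n_reference,n_detected,nt,nc,no,recall_pct,precision_pct,f_score
A1,als,37,27,25,2,12,67.57,92.59,0.78
A1,tls,37,36,32,4,5,86.49,88.89,0.88
A1,merged,37,40,36,4,1,97.30,90.00,0.94
A2,als,45,32,26,6,19,57.78,81.25,0.68
A2,tls,45,42,35,7,10,77.78,83.33,0.80
A2,merged,45,50,42,8,3,93.33,84.00,0.88
A3,als,52,38,29,9,23,55.77,76.32,0.64
A3,tls,52,52,40,12,12,76.92,76.92,0.77
A3,merged,52,55,44,11,8,84.62,80.00,0.82
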