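dataset,model,preprocessing,cal_acc,val_acc,test_acc,precision,recall,f1,auc
DS_Jopung,LDA,msc,96.45,96.49,96.74,0.968,0.967,0.966,0.995
DS_Jopung,SVM,msc,96.72,95.68,97.57,0.979,0.976,0.977,0.997
DS_Jopung,PLS-DA,sg_2nd,99.27,98.84,99.42,0.986,0.988,0.987,0.999
SPA_DS_Jopung,LDA,msc,97.73,97.67,97.34,0.977,0.977,0.977,0.990
SPA_DS_Jopung,SVM,sg_smooth,94.03,93.00,93.96,0.941,0.940,0.939,0.992
SPA_DS_Jopung,PLS-DA,sg_2nd,98.22,97.98,98.22,0.982,0.982,0.982,0.999
DS_Superior,LDA,max_norm,96.68,95.68,95.28,0.955,0.953,0.953,0.996
DS_Superior,SVM,sg_smooth,96.39,95.63,94.98,0.952,0.950,0.951,0.993
DS_Superior,PLS-DA,raw,98.34,97.34,96.71,0.970,0.967,0.968,0.998
SPA_DS_Superior,LDA,mean_norm,91.10,89.43,91.58,0.927,0.916,0.918,0.986
SPA_DS_Superior,SVM,raw,92.51,91.65,89.79,0.904,0.898,0.899,0.978
SPA_DS_Superior,PLS-DA,raw,94.44,93.54,94.14,0.943,0.941,0.941,0.989
DS_Jopung_Superior,PLS-DA,range_norm,95.68,93.20,94.18,0.949,0.942,0.944,0.993
SPA_DS_Jopung_Superior,PLS-DA,range_norm,93.26,90.46,91.04,0.916,0.910,0.912,0.981
TS_Jopung,LDA,max_norm,97.92,96.55,97.32,0.978,0.973,0.975,0.994
TS_Jopung,SVM,range_norm,96.69,96.59,95.95,0.968,0.960,0.963,0.997
TS_Jopung,PLS-DA,raw,98.01,98.94,98.10,0.986,0.981,0.983,0.998
SPA_TS_Jopung,LDA,max_norm,91.25,90.94,90.64,0.926,0.906,0.911,0.987
SPA_TS_Jopung,SVM,range_norm,90.54,90.49,89.44,0.924,0.894,0.902,0.988
SPA_TS_Jopung,PLS-DA,raw,96.73,95.38,96.26,0.973,0.963,0.966,0.996
TS_Superior,LDA,sg_2nd,96.24,95.80,95.12,0.954,0.951,0.950,0.989
TS_Superior,SVM,sg_2nd,96.43,95.60,96.36,0.965,0.964,0.963,0.997
TS_Superior,PLS-DA,range_norm,99.40,99.50,99.34,0.994,0.993,0.994,0.999
SPA_TS_Superior,LDA,range_norm,94.39,94.59,92.52,0.933,0.925,0.926,0.991
SPA_TS_Superior,SVM,range_norm,94.79,93.41,94.55,0.951,0.946,0.947,0.993
SPA_TS_Superior,PLS-DA,msc,97.19,96.54,96.40,0.965,0.964,0.963,0.997
TS_Jopung_Superior,PLS-DA,raw,94.72,93.56,93.99,0.944,0.940,0.939,0.998
SPA_TS_Jopung_Superior,PLS-DA,raw,91.34,91.62,91.50,0.924,0.913,0.916,0.986
DS_Jinyulmi,LDA,sg_2nd,92.77,92.01,92.86,0.931,0.929,0.929,0.988
DS_Jinyulmi,SVM,sg_2nd,91.80,91.45,92.47,0.913,0.905,0.907,0.989
DS_Jinyulmi,PLS-DA,raw,99.56,99.84,99.45,0.995,0.995,0.995,0.999
SPA_DS_Jinyulmi,LDA,range_norm,90.72,90.13,90.89,0.914,0.909,0.908,0.987
SPA_DS_Jinyulmi,SVM,raw,91.66,92.45,90.59,0.915,0.906,0.908,0.987
SPA_DS_Jinyulmi,PLS-DA,msc,95.23,93.86,95.23,0.955,0.952,0.953,0.989
EWS_Jinyulmi,LDA,range_norm,96.06,94.62,95.08,0.978,0.978,0.978,0.998
EWS_Jinyulmi,SVM,snv,96.32,96.34,95.48,0.955,0.955,0.955,0.996
EWS_Jinyulmi,PLS-DA,range_norm,98.99,98.13,97.81,0.978,0.978,0.978,0.998
SPA_EWS_Jinyulmi,LDA,snv,88.08,87.22,87.18,0.875,0.872,0.872,0.975
SPA_EWS_Jinyulmi,SVM,snv,89.00,88.99,90.33,0.905,0.903,0.903,0.977
SPA_EWS_Jinyulmi,PLS-DA,raw,90.83,89.83,90.53,0.908,0.905,0.906,0.978
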