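signs,scheme,classifier,AC,SN,SP
27,holdout_70_30,ANFIS-HB,74.79,65.63,78.16
27,holdout_80_20,ANFIS-HB,81.25,72.22,83.87
27,kfold_10,ANFIS-HB,81.38,69.82,86.06
27,kfold_5,ANFIS-HB,78.86,65.80,84.28
27,holdout_70_30,ANFIS-BP,84.87,71.79,91.25
27,holdout_80_20,ANFIS-BP,85.00,66.67,90.32
27,kfold_10,ANFIS-BP,82.68,64.74,90.60
27,kfold_5,ANFIS-BP,82.92,65.83,89.76
27,holdout_70_30,DNN,84.99,76.65,89.23
27,holdout_80_20,DNN,87.50,77.84,92.44
27,kfold_10,DNN,87.65,78.08,91.76
27,kfold_5,DNN,88.19,75.88,93.03
27,holdout_70_30,ANFIS-GA,89.08,89.29,89.01
27,holdout_80_20,ANFIS-GA,88.75,83.33,90.32
27,kfold_10,ANFIS-GA,85.68,74.99,89.93
27,kfold_5,ANFIS-GA,86.42,79.96,89.58
13,holdout_70_30,ANFIS-HB,80.67,66.67,86.05
13,holdout_80_20,ANFIS-HB,82.50,76.00,85.45
13,kfold_10,ANFIS-HB,82.64,74.17,86.26
13,kfold_5,ANFIS-HB,80.15,66.95,85.58
13,holdout_70_30,ANFIS-BP,84.87,72.73,89.53
13,holdout_80_20,ANFIS-BP,86.25,80.00,89.09
13,kfold_10,ANFIS-BP,88.49,82.04,91.33
13,kfold_5,ANFIS-BP,84.17,67.70,90.86
13,holdout_70_30,DNN,85.83,74.60,91.62
13,holdout_80_20,DNN,88.75,80.92,92.72
13,kfold_10,DNN,88.65,80.32,91.34
13,kfold_5,DNN,88.71,78.36,92.77
13,holdout_70_30,ANFIS-GA,89.92,84.85,91.86
13,holdout_80_20,ANFIS-GA,90.00,84.00,92.73
13,kfold_10,ANFIS-GA,88.67,79.77,92.59
13,kfold_5,ANFIS-GA,88.42,75.03,93.61
8,holdout_70_30,ANFIS-HB,73.11,47.37,85.19
8,holdout_80_20,ANFIS-HB,78.75,55.56,85.48
8,kfold_10,ANFIS-HB,77.88,58.70,85.65
8,kfold_5,ANFIS-HB,79.63,59.75,87.28
8,holdout_70_30,ANFIS-BP,76.47,55.26,86.42
8,holdout_80_20,ANFIS-BP,85.00,61.11,91.94
8,kfold_10,ANFIS-BP,81.89,63.71,88.61
8,kfold_5,ANFIS-BP,83.43,64.78,90.90
8,holdout_70_30,DNN,82.49,79.70,83.84
8,holdout_80_20,DNN,83.75,81.84,84.59
8,kfold_10,DNN,84.60,73.52,89.47
8,kfold_5,DNN,85.16,74.47,90.23
8,holdout_70_30,ANFIS-GA,84.87,73.68,90.12
8,holdout_80_20,ANFIS-GA,86.25,83.33,87.10
8,kfold_10,ANFIS-GA,83.66,71.20,89.16
8,kfold_5,ANFIS-GA,84.44,65.65,91.92
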