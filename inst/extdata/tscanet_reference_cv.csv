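model,fold1,fold2,fold3,fold4,fold5,mean,std
EEG-Net,85.31,86.80,85.09,83.82,85.23,85.24,1.06
EEG-TCNet,85.33,86.83,85.10,83.48,85.10,85.17,1.19
GRU,84.50,86.47,88.20,87.59,86.73,86.70,1.41
LSTM,88.91,87.63,90.36,87.88,90.25,89.01,1.28
S3T,87.32,91.79,87.98,86.74,88.65,88.50,1.98
R-Transformer,85.92,83.86,86.23,86.55,87.82,86.08,1.43
ViT,85.76,85.92,85.59,88.71,82.12,85.62,2.34
TSCA-Net,94.30,92.56,92.41,91.77,92.25,92.66,0.96
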