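grid,variant,accuracy
components,no-TF-LSTM,88.79
components,no-TF-Transformer,88.61
components,no-SF,91.86
components,no-TSCross,89.87
components,no-SingleC,92.41
components,no-SingleT,91.45
components,full,94.30
position,position-absolute,91.30
position,position-sincos,90.95
position,position-none,91.74
position,position-relative,94.30
heads-dims,heads8-dims64,91.58
heads-dims,heads8-dims128,91.83
heads-dims,heads8-dims256,92.22
heads-dims,heads16-dims64,92.06
heads-dims,heads16-dims128,94.30
heads-dims,heads16-dims256,93.19
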