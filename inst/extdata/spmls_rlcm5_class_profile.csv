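item,C1,C2,C3,C4,C5
pc,0.12,0.04,0.40,0.07,0.37
SPM1,0.39,0.39,0.83,0.83,0.83
SPM2,0.57,0.57,0.99,0.86,0.99
SPM3,0.33,0.00,0.86,0.96,0.96
SPM4,0.05,1.00,0.91,0.60,1.00
SPM5,0.08,1.00,0.96,0.77,1.00
SPM6,0.07,0.07,0.85,0.85,0.97
SPM7,0.20,0.83,0.58,0.83,0.95
SPM8,0.06,0.69,0.36,1.00,0.90
SPM9,0.16,0.34,0.34,1.00,0.90
SPM10,0.00,0.23,0.23,0.00,0.79
SPM11,0.14,0.00,0.14,0.00,0.77
SPM12,0.11,0.62,0.11,0.11,0.62
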