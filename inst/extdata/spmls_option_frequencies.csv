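item,category,percent,original_code
SPM1,0,76.0,7
SPM1,1,13.6,3
SPM1,2,3.0,1
SPM1,3,2.4,4
SPM1,4,2.2,6
SPM1,5,2.0,2
SPM1,6,0.8,5
SPM2,0,91.0,6
SPM2,1,3.0,3
SPM2,2,2.4,4
SPM2,3,2.2,1
SPM2,4,0.8,5
SPM2,5,0.4,7
SPM2,6,0.2,2
SPM3,0,80.4,8
SPM3,1,8.0,2
SPM3,2,4.2,6
SPM3,3,2.0,4
SPM3,4,1.8,3
SPM3,5,1.6,5
SPM3,6,1.2,7
SPM3,7,0.8,1
SPM4,0,82.4,2
SPM4,1,5.6,3
SPM4,2,3.2,5
SPM4,3,2.6,1
SPM4,4,2.2,8
SPM4,5,1.8,6
SPM4,6,1.2,7
SPM4,7,1.0,4
SPM5,0,85.6,1
SPM5,1,3.8,2
SPM5,2,3.0,3
SPM5,3,2.6,7
SPM5,4,1.8,6
SPM5,5,1.6,5
SPM5,6,1.0,4
SPM5,7,0.6,8
SPM6,0,76.4,5
SPM6,1,7.0,4
SPM6,2,5.2,6
SPM6,3,3.0,3
SPM6,4,2.8,7
SPM6,5,2.6,8
SPM6,6,2.0,2
SPM6,7,1.0,1
SPM7,0,70.1,1
SPM7,1,6.6,4
SPM7,2,5.8,5
SPM7,3,5.4,3
SPM7,4,4.4,8
SPM7,5,3.4,6
SPM7,6,2.4,7
SPM7,7,1.8,2
SPM8,0,58.1,6
SPM8,1,7.6,1
SPM8,2,7.0,3
SPM8,3,6.6,8
SPM8,4,6.4,2
SPM8,5,6.2,5
SPM8,6,5.8,7
SPM8,7,2.2,4
SPM9,0,57.3,3
SPM9,1,12.0,5
SPM9,2,9.0,1
SPM9,3,7.2,4
SPM9,4,6.6,8
SPM9,5,4.0,7
SPM9,6,3.0,2
SPM9,7,0.8,6
SPM10,0,39.5,2
SPM10,1,17.2,6
SPM10,2,11.2,7
SPM10,3,8.0,3
SPM10,4,7.8,8
SPM10,5,7.4,5
SPM10,6,6.0,4
SPM10,7,2.8,1
SPM11,0,35.7,4
SPM11,1,14.0,1
SPM11,2,13.8,7
SPM11,3,9.8,5
SPM11,4,9.4,6
SPM11,5,8.0,3
SPM11,6,6.6,2
SPM11,7,2.6,8
SPM12,0,32.5,5
SPM12,1,15.4,2
SPM12,2,14.2,3
SPM12,3,10.4,1
SPM12,4,8.2,4
SPM12,5,8.2,7
SPM12,6,7.4,6
SPM12,7,3.6,8
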