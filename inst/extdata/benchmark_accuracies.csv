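model,Caltech7,Handwritten,Dermatology,Forest,EEG
TSK-FS,0.9153,0.9100,0.9075,0.8275,0.6050
HTSK,0.9390,0.9700,0.9600,0.8300,0.6750
MBGD-RDA,0.9356,0.9600,0.9700,0.8475,0.6650
TSK-MBGD-UR,0.9254,0.9600,0.9550,0.8818,0.5950
TSK-MBGD-BN,0.9254,0.9675,0.9324,0.8853,0.6000
HTSK-LN,0.9390,0.9500,0.9650,0.8324,0.6450
HTSK-LN-RELU,0.9322,0.9700,0.9600,0.8500,0.6550
DMCCA-TSK,0.9288,0.9100,0.9375,0.8514,0.4200
DGCCA-TSK,0.9390,0.8900,0.8650,0.8514,0.6150
DTCCA-TSK,0.9254,0.9400,0.8950,0.8243,0.5700
DCCAEG-TSK,0.9119,0.9300,0.9075,0.8485,0.6600
MVD-TSK-FS,0.9322,0.9100,0.9772,0.8581,0.5750
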