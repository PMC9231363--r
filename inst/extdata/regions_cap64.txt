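# 13-region scheme for the 64-channel competition cap.
# One region per line: name: comma-separated channel names.
prefrontal: Fp1,Fpz,Fp2,AF3,AFz,AF4
frontal_left: AF7,F7,F5
frontal_right: AF8,F8,F6
frontal_mid: F3,F1,Fz,F2,F4
frontocentral_left: FT7,FC5,FC3
frontocentral_mid: FC1,FCz,FC2
frontocentral_right: FC4,FC6,FT8
temporal_left: T9,T7,C5,TP7
temporal_right: T10,T8,C6,TP8
central: C3,C1,Cz,C2,C4
centroparietal: CP5,CP3,CP1,CPz,CP2,CP4,CP6
parietal: P7,P5,P3,P1,Pz,P2,P4,P6,P8
parietooccipital: PO7,PO3,POz,PO4,PO8,O1,Oz,O2,Iz
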