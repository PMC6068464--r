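name,copies,lifetime_days
VAMP2,70,5.2
Synaptophysin,32,4.1
Synaptotagmin1,15,4.6
Rab3a,10,3.4
VGlut1,9,5.9
SV2,2,6.3
vATPase,1,7.1
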