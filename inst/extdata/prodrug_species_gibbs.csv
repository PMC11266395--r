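method,solvent,label,energy,repeat_id
HF,with,4,-1221.2446,
HF,with,5,-343.3933,
HF,with,6,-801.8703,
HF,with,TS,-1221.2238,
HF,with,H2O,-76.0465,
HF,without,4,-1221.1821,
HF,without,5,-343.3805,
HF,without,6,-801.8576,
HF,without,TS,-1221.178,
HF,without,H2O,-76.0385,
CASCI,with,4,-1221.2447,
CASCI,with,5,-343.4038,
CASCI,with,6,-801.8732,
CASCI,with,TS,-1221.2259,
CASCI,with,H2O,-76.0466,
CASCI,without,4,-1221.1821,
CASCI,without,5,-343.3912,
CASCI,without,6,-801.8607,
CASCI,without,TS,-1221.180,
CASCI,without,H2O,-76.0386,
VQE,with,4,-1221.240,1
VQE,with,4,-1221.243,2
VQE,with,4,-1221.227,3
VQE,with,4,-1221.242,4
VQE,with,5,-343.395,1
VQE,with,5,-343.426,2
VQE,with,5,-343.403,3
VQE,with,5,-343.407,4
VQE,with,6,-801.866,1
VQE,with,6,-801.878,2
VQE,with,6,-801.859,3
VQE,with,6,-801.866,4
VQE,with,TS,-1221.224,1
VQE,with,TS,-1221.232,2
VQE,with,TS,-1221.223,3
VQE,with,TS,-1221.230,4
VQE,with,H2O,-76.043,1
VQE,with,H2O,-76.059,2
VQE,with,H2O,-76.036,3
VQE,with,H2O,-76.041,4
VQE,without,4,-1221.177,1
VQE,without,4,-1221.180,2
VQE,without,4,-1221.18,3
VQE,without,4,-1221.186,4
VQE,without,5,-343.390,1
VQE,without,5,-343.390,2
VQE,without,5,-343.391,3
VQE,without,5,-343.390,4
VQE,without,6,-801.856,1
VQE,without,6,-801.839,2
VQE,without,6,-801.857,3
VQE,without,6,-801.852,4
VQE,without,TS,-1221.181,1
VQE,without,TS,-1221.187,2
VQE,without,TS,-1221.179,3
VQE,without,TS,-1221.207,4
VQE,without,H2O,-76.029,1
VQE,without,H2O,-76.035,2
VQE,without,H2O,-76.059,3
VQE,without,H2O,-76.053,4
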