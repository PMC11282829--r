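gene	n_datasets
ACKR3	5
ADGRA2	5
ADGRA3	5
ADGRE5	5
ADGRG1	5
ADRA2C	5
C5AR1	5
CXCR4	5
F2R	5
FPR3	5
GPRC5A	5
GPRC5B	5
PTAFR	5
S1PR2	5
SMO	5
ADGRF5	4
ADGRG2	4
CCR1	4
CELSR1	4
CELSR2	4
CYSLTR1	4
GPR157	4
GPR183	4
GPRC5C	4
LGR4	4
LGR6	4
LPAR2	4
LPAR3	4
LPAR6	4
OPN3	4
ADGRL1	3
ADGRL2	3
C5AR2	3
CCR5	3
EDNRA	3
F2RL1	3
GPR34	3
GPR82	3
GPR89B	3
HCAR1	3
LGR5	3
MC1R	3
PTGIR	3
PTH2R	3
TBXA2R	3
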