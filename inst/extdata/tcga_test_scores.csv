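tcga_id,score,reference_label
TCGA-55-6979-01Z-00-DX1,0.025260,Immunity_L
TCGA-55-6975-01Z-00-DX1,0.015157,Immunity_L
TCGA-55-6972-01Z-00-DX1,0.005871,Immunity_L
TCGA-44-5645-01Z-00-DX1,0.058781,Immunity_H
TCGA-44-6778-01Z-00-DX1,0.053232,Immunity_H
TCGA-44-2665-01Z-00-DX1,0.042932,Immunity_L
TCGA-44-3398-01Z-00-DX1,0.034461,Immunity_L
TCGA-44-2661-01Z-00-DX1,0.082299,Immunity_L
TCGA-49-4490-01Z-00-DX1,0.020078,Immunity_L
TCGA-44-6145-01Z-00-DX1,0.064477,Immunity_H
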