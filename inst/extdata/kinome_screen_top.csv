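kinase,pct_ctrl
BTK,3.0
TEC,7.8
BMX,11.0
HUNK,11.0
RIPK2,33.0
JAK3,58.0
EGFR,72.0
ITK,85.0
LCK,91.0
SRC,97.0
ABL1,99.0
AURKA,100.0
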