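"","OH","CH","FH","EH","PR","SU","SG","FG","AG","PO","RST"
"OH",98.36,0.16,0.08,0,0.08,0.25,0.16,0.08,0.25,0.41,0.16
"CH",0.25,97.79,0.08,0.08,0,0,0.66,0,0.66,0.33,0.16
"FH",0.16,0,99.26,0,0.33,0,0,0,0,0.16,0.08
"EH",0.16,0.08,0,99.51,0,0,0.08,0.16,0,0,0
"PR",0.49,0,0.16,0,98.93,0.08,0,0.08,0.08,0.16,0
"SU",0.33,0.08,0,0.16,0.08,98.77,0.16,0.08,0.16,0.16,0
"SG",0.74,0.49,0,0.08,0.33,0,95.33,0.9,1.07,1.07,0
"FG",0.66,0.41,0.08,0.16,1.23,0.25,1.88,94.43,0.33,0.57,0
"AG",0.33,0.81,0.08,0,0.08,0.33,0.66,0.16,95.9,1.64,0
"PO",0.25,0.82,0.25,0.08,0.25,0.33,0.33,0.16,1.31,96.23,0
"RST",0.49,0.25,0.08,0,0.33,0,0.9,0.16,0.41,0.16,97.21
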