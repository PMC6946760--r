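"","OH","CH","FH","EH","PR","SU","SG","FG","AG","PO","RST"
"OH",95.33,0.49,0.16,0.08,0.25,0.98,0.25,0.41,0.57,0.9,0.57
"CH",0.41,95.66,0,0.08,0,0.66,0.82,0.57,0.98,0.41,0.41
"FH",0.25,0,98.28,0,0.49,0.08,0.08,0.16,0.16,0.16,0.33
"EH",0.08,0.08,0,98.93,0.08,0.08,0.25,0.49,0,0,0
"PR",0.25,0,0.08,0,98.11,0.25,0.33,0.66,0.16,0.08,0.08
"SU",0.66,0.49,0.08,0,0.16,96.39,0.41,0.66,0.66,0.25,0.25
"SG",0.74,0.49,0,0,0.49,0.16,91.31,3.61,0.82,1.39,0.98
"FG",0,0.66,0.08,0.08,0.74,0.25,3.03,93.36,0.49,0.9,0.41
"AG",0.66,1.23,0.16,0,0.08,0.9,0.49,0.82,93.28,2.3,0.08
"PO",1.15,0.41,0.16,0,0.25,0.49,1.64,0.98,2.13,91.8,0.98
"RST",0.16,0.16,0.16,0,0,0,0.74,0.49,0,0.57,97.7
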