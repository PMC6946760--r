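"","OH","CH","FH","EH","PR","SU","SG","FG","AG","PO","RST"
"OH",87.46,0.33,0,0.08,1.64,0.98,1.97,1.72,1.97,2.7,1.15
"CH",0.41,85.66,0,0.33,0.98,0.25,4.26,2.62,2.54,2.3,0.57
"FH",0.66,0.16,97.46,0,0.49,0,0.08,0.16,0,0.41,0.33
"EH",1.15,0.74,0,95.25,0,0,0.41,0.57,1.15,0,0
"PR",3.28,0.74,0.33,0,88.11,2.13,1.56,1.64,1.15,0.33,0
"SU",0.74,0.25,0,0,0.57,90.33,0.33,2.21,2.7,1.72,0.98
"SG",1.64,1.39,0,0,0.82,0.41,84.43,5.9,2.3,1.39,1.64
"FG",0.49,1.39,0,0,0.74,0.66,5.98,86.39,1.8,0.66,1.89
"AG",1.39,0.74,0,0,0,2.13,1.39,1.8,88.28,2.13,1.15
"PO",1.23,1.56,0,0,0.08,1.64,1.23,3.03,1.15,88.2,1.8
"RST",0.08,0.16,0,0,0,0,0,0,0,0,98.52
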