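series,varied,partners,level,ic,ci_printed
berberine,berberine,,10,0.27,
berberine,berberine,,20,0.51,
berberine,berberine,,30,0.76,
berberine,berberine,,40,1.08,
berberine,berberine,,50,1.48,
berberine,berberine,,60,2.02,
berberine,berberine,,70,2.85,
berberine,berberine,,80,4.32,
berberine,berberine,,90,8.09,
berberine+coptisine,berberine,coptisine,10,0.051,0.24
berberine+coptisine,berberine,coptisine,20,0.11,0.33
berberine+coptisine,berberine,coptisine,30,0.18,0.43
berberine+coptisine,berberine,coptisine,40,0.28,0.55
berberine+coptisine,berberine,coptisine,50,0.4,0.7
berberine+coptisine,berberine,coptisine,60,0.59,0.91
berberine+coptisine,berberine,coptisine,70,0.9,1.26
berberine+coptisine,berberine,coptisine,80,1.5,1.92
berberine+coptisine,berberine,coptisine,90,3.22,3.79
berberine+palmatine,berberine,palmatine,10,0.031,0.12
berberine+palmatine,berberine,palmatine,20,0.08,0.18
berberine+palmatine,berberine,palmatine,30,0.15,0.24
berberine+palmatine,berberine,palmatine,40,0.24,0.29
berberine+palmatine,berberine,palmatine,50,0.37,0.36
berberine+palmatine,berberine,palmatine,60,0.59,0.47
berberine+palmatine,berberine,palmatine,70,0.96,0.62
berberine+palmatine,berberine,palmatine,80,1.75,0.92
berberine+palmatine,berberine,palmatine,90,4.33,1.81
berberine+coptisine+palmatine,berberine,coptisine;palmatine,10,0.027,0.14
berberine+coptisine+palmatine,berberine,coptisine;palmatine,20,0.066,0.22
berberine+coptisine+palmatine,berberine,coptisine;palmatine,30,0.12,0.32
berberine+coptisine+palmatine,berberine,coptisine;palmatine,40,0.19,0.43
berberine+coptisine+palmatine,berberine,coptisine;palmatine,50,0.31,0.62
berberine+coptisine+palmatine,berberine,coptisine;palmatine,60,0.48,0.88
berberine+coptisine+palmatine,berberine,coptisine;palmatine,70,0.78,1.32
berberine+coptisine+palmatine,berberine,coptisine;palmatine,80,1.42,2.24
berberine+coptisine+palmatine,berberine,coptisine;palmatine,90,3.47,5.1
coptisine,coptisine,,10,0.6,
coptisine,coptisine,,20,0.79,
coptisine,coptisine,,30,0.95,
coptisine,coptisine,,40,1.11,
coptisine,coptisine,,50,1.27,
coptisine,coptisine,,60,1.46,
coptisine,coptisine,,70,1.69,
coptisine,coptisine,,80,2.04,
coptisine,coptisine,,90,2.68,
coptisine+berberine,coptisine,berberine,10,0.12,0.36
coptisine+berberine,coptisine,berberine,20,0.26,0.67
coptisine+berberine,coptisine,berberine,30,0.44,1.04
coptisine+berberine,coptisine,berberine,40,0.67,1.49
coptisine+berberine,coptisine,berberine,50,1,2.11
coptisine+berberine,coptisine,berberine,60,1.49,2.98
coptisine+berberine,coptisine,berberine,70,2.3,4.39
coptisine+berberine,coptisine,berberine,80,3.91,7.06
coptisine+berberine,coptisine,berberine,90,8.67,14.6
coptisine+palmatine,coptisine,palmatine,10,0.13,0.25
coptisine+palmatine,coptisine,palmatine,20,0.3,0.47
coptisine+palmatine,coptisine,palmatine,30,0.52,0.7
coptisine+palmatine,coptisine,palmatine,40,0.82,0.98
coptisine+palmatine,coptisine,palmatine,50,1.23,1.33
coptisine+palmatine,coptisine,palmatine,60,1.86,1.82
coptisine+palmatine,coptisine,palmatine,70,2.9,2.57
coptisine+palmatine,coptisine,palmatine,80,5.01,3.93
coptisine+palmatine,coptisine,palmatine,90,11.4,7.6
coptisine+berberine+palmatine,coptisine,berberine;palmatine,10,0.13,0.43
coptisine+berberine+palmatine,coptisine,berberine;palmatine,20,0.29,0.83
coptisine+berberine+palmatine,coptisine,berberine;palmatine,30,0.47,1.25
coptisine+berberine+palmatine,coptisine,berberine;palmatine,40,0.73,1.83
coptisine+berberine+palmatine,coptisine,berberine;palmatine,50,1.08,2.59
coptisine+berberine+palmatine,coptisine,berberine;palmatine,60,1.6,3.67
coptisine+berberine+palmatine,coptisine,berberine;palmatine,70,2.44,5.37
coptisine+berberine+palmatine,coptisine,berberine;palmatine,80,4.11,8.63
coptisine+berberine+palmatine,coptisine,berberine;palmatine,90,8.97,17.8
palmatine,palmatine,,10,1.73,
palmatine,palmatine,,20,2.6,
palmatine,palmatine,,30,3.4,
palmatine,palmatine,,40,4.25,
palmatine,palmatine,,50,5.21,
palmatine,palmatine,,60,6.39,
palmatine,palmatine,,70,7.97,
palmatine,palmatine,,80,10.4,
palmatine,palmatine,,90,15.7,
palmatine+berberine,palmatine,berberine,10,0.25,0.47
palmatine+berberine,palmatine,berberine,20,0.67,1.14
palmatine+berberine,palmatine,berberine,30,1.28,2.06
palmatine+berberine,palmatine,berberine,40,2.18,3.38
palmatine+berberine,palmatine,berberine,50,3.54,5.34
palmatine+berberine,palmatine,berberine,60,5.77,8.49
palmatine+berberine,palmatine,berberine,70,9.81,14.1
palmatine+berberine,palmatine,berberine,80,18.7,26.4
palmatine+berberine,palmatine,berberine,90,49.6,68.5
palmatine+coptisine,palmatine,coptisine,10,0.37,0.44
palmatine+coptisine,palmatine,coptisine,20,0.96,0.76
palmatine+coptisine,palmatine,coptisine,30,1.82,1.1
palmatine+coptisine,palmatine,coptisine,40,3.08,1.49
palmatine+coptisine,palmatine,coptisine,50,5,1.97
palmatine+coptisine,palmatine,coptisine,60,8.11,2.6
palmatine+coptisine,palmatine,coptisine,70,13.7,3.54
palmatine+coptisine,palmatine,coptisine,80,26.1,5.13
palmatine+coptisine,palmatine,coptisine,90,68.8,8.99
palmatine+berberine+coptisine,palmatine,berberine;coptisine,10,0.43,1.27
palmatine+berberine+coptisine,palmatine,berberine;coptisine,20,1.06,2.92
palmatine+berberine+coptisine,palmatine,berberine;coptisine,30,1.95,5.19
palmatine+berberine+coptisine,palmatine,berberine;coptisine,40,3.2,8.33
palmatine+berberine+coptisine,palmatine,berberine;coptisine,50,5.05,12.9
palmatine+berberine+coptisine,palmatine,berberine;coptisine,60,7.97,20.12
palmatine+berberine+coptisine,palmatine,berberine;coptisine,70,13.1,32.7
palmatine+berberine+coptisine,palmatine,berberine;coptisine,80,24,59.2
palmatine+berberine+coptisine,palmatine,berberine;coptisine,90,59.8,145
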