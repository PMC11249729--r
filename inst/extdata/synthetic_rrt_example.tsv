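TTT	0.781350825020473
TTC	0.980292941151913
TTA	0.736902289190694
TTG	1.45550753539126
TCT	1.02115895522127
TCC	0.740036987609084
TCA	1.0673256971767
TCG	1.14500265320337
TAT	1.09405919929681
TAC	0.854847052828289
TGT	1.42187264080503
TGC	1.03855688917234
TGG	0.782492199133346
CTT	0.50085435355246
CTC	1.27590622884421
CTA	0.919518262544658
CTG	0.926948531166715
CCT	1.21282236407014
CCC	1.17189016559776
CCA	1.09962411384085
CCG	1.20440985588686
CAT	1.15913518972948
CAC	0.950805491469528
CAA	0.533475336957973
CAG	1.10763514899363
CGT	0.916640419848046
CGC	0.891413650440493
CGA	0.616846771260342
CGG	0.814479533733386
ATT	1.04675999411768
ATC	1.36220718069082
ATA	0.904742843146171
ATG	1.03792558146046
ACT	0.917237012895082
ACC	0.633243256533772
ACA	0.829010514189492
ACG	0.833830487013595
AAT	0.915823412227634
AAC	1.26703958118132
AAA	1.15299769983268
AAG	0.889237815560491
AGT	0.867391164637619
AGC	1.13181867051078
AGA	1.08821825724851
AGG	0.767838727823668
GTT	0.763820391453663
GTC	1.03123693157448
GTA	1.15472850488824
GTG	0.90232464878621
GCT	1.19170636496783
GCC	1.04096241396348
GCA	0.784513613918755
GCG	1.02448449090603
GAT	0.678720663434679
GAC	1.39086057358006
GAA	1.62123468203
GAG	0.840174242897407
GGT	0.69511244259779
GGC	1.09220384643316
GGA	0.896605554409094
GGG	1.82417715195223
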