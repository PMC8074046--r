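pathogen,mic_mg_l,count
Escherichia coli,0.008,1240
Escherichia coli,0.016,7921
Escherichia coli,0.032,4616
Escherichia coli,0.064,701
Escherichia coli,0.125,132
Escherichia coli,0.25,36
Escherichia coli,0.5,15
Escherichia coli,1,9
Escherichia coli,2,6
Escherichia coli,4,4
Escherichia coli,8,5
Streptococcus pneumoniae,0.008,902
Streptococcus pneumoniae,0.016,2734
Streptococcus pneumoniae,0.032,1371
Streptococcus pneumoniae,0.064,292
Streptococcus pneumoniae,0.125,161
Streptococcus pneumoniae,0.25,89
Streptococcus pneumoniae,0.5,60
Streptococcus pneumoniae,1,28
Klebsiella pneumoniae,0.016,1551
Klebsiella pneumoniae,0.032,2659
Klebsiella pneumoniae,0.064,1143
Klebsiella pneumoniae,0.125,312
Klebsiella pneumoniae,0.25,94
Klebsiella pneumoniae,0.5,42
Klebsiella pneumoniae,1,35
Klebsiella pneumoniae,2,26
Klebsiella pneumoniae,4,21
Klebsiella pneumoniae,8,30
Klebsiella pneumoniae,16,43
Staphylococcus aureus,0.032,601
Staphylococcus aureus,0.064,1815
Staphylococcus aureus,0.125,3295
Staphylococcus aureus,0.25,2232
Staphylococcus aureus,0.5,640
Staphylococcus aureus,1,120
Staphylococcus aureus,2,41
Staphylococcus aureus,4,19
Staphylococcus aureus,8,25
Pseudomonas aeruginosa,0.064,121
Pseudomonas aeruginosa,0.125,530
Pseudomonas aeruginosa,0.25,1587
Pseudomonas aeruginosa,0.5,2802
Pseudomonas aeruginosa,1,2545
Pseudomonas aeruginosa,2,1599
Pseudomonas aeruginosa,4,857
Pseudomonas aeruginosa,8,601
Pseudomonas aeruginosa,16,512
Pseudomonas aeruginosa,32,401
Acinetobacter baumannii,0.064,140
Acinetobacter baumannii,0.125,480
Acinetobacter baumannii,0.25,1230
Acinetobacter baumannii,0.5,1120
Acinetobacter baumannii,1,640
Acinetobacter baumannii,2,330
Acinetobacter baumannii,4,180
Acinetobacter baumannii,8,160
Acinetobacter baumannii,16,210
Acinetobacter baumannii,32,250
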