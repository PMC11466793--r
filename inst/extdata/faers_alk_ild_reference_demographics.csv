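section,level,crizotinib,ceritinib,alectinib,brigatinib,lorlatinib
total,total,294,51,157,94,44
age,18-64,127,23,53,34,23
age,65-84,108,14,60,32,12
age,>=85,4,0,1,2,1
age,unknown,55,14,43,26,8
sex,male,131,21,80,30,25
sex,female,140,23,62,48,16
sex,unknown,23,7,15,16,3
source,physician,191,13,105,58,28
source,pharmacist,25,3,13,6,4
source,consumer,35,18,20,14,6
source,other,42,16,19,16,5
source,unknown,1,1,0,0,1
outcome,hospitalization,166,24,71,56,20
outcome,disability,10,1,1,1,0
outcome,life-threatening,51,6,13,7,6
outcome,death,98,11,18,15,14
outcome,other,149,17,31,22,20
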