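group,sex,class,count,count_lo,count_hi,pct,pct_lo,pct_hi,total
known,male,SCC,585,NA,NA,32.3,30.1,34.4,1812
known,male,ADCA,908,NA,NA,50.1,47.8,52.4,1812
known,male,OTHER,219,NA,NA,17.6,15.0,20.2,1812
known,female,SCC,93,NA,NA,12.5,10.1,14.8,747
known,female,ADCA,583,NA,NA,78.0,75.1,81.0,747
known,female,OTHER,71,NA,NA,9.5,6.4,12.5,747
imputed,male,SCC,296,263,309,32.1,28.5,35.5,922
imputed,male,ADCA,482,454,517,52.3,49.3,56.1,922
imputed,male,OTHER,144,111,175,15.6,12.0,19.0,922
imputed,female,SCC,48,35,61,13.2,9.6,16.8,363
imputed,female,ADCA,281,264,297,77.3,72.7,81.8,363
imputed,female,OTHER,34,20,51,9.5,5.5,14.1,363
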