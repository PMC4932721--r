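block,sex,level,count,pct,total
histology,male,SCC,585,21.4,2734
histology,male,ADCA,908,33.2,2734
histology,male,NSCC_NOS,131,4.8,2734
histology,male,OTHER,219,10.7,2734
histology,male,UNKNOWN,791,28.9,2734
histology,female,SCC,93,8.4,1110
histology,female,ADCA,583,52.5,1110
histology,female,NSCC_NOS,41,3.7,1110
histology,female,OTHER,71,6.4,1110
histology,female,UNKNOWN,322,29.0,1110
religion,male,buddhist_other,2328,85.1,2734
religion,male,muslim,406,14.9,2734
religion,female,buddhist_other,1004,90.4,1110
religion,female,muslim,106,9.6,1110
district,male,Muang Songkhla,455,16.6,2734
district,male,Sathing Phra,101,3.7,2734
district,male,Chana,194,7.1,2734
district,male,Na Thawi,135,4.9,2734
district,male,Thepha,116,4.2,2734
district,male,Saba Yoi,64,2.3,2734
district,male,Ranot,150,5.5,2734
district,male,Krasae Sin,30,1.1,2734
district,male,Rattaphum,113,4.1,2734
district,male,Sadao,265,9.7,2734
district,male,Hat Yai,782,28.6,2734
district,male,Na Mom,47,1.7,2734
district,male,Khuan Niang,58,2.1,2734
district,male,Bang Klam,45,1.6,2734
district,male,Singhanakhon,141,5.2,2734
district,male,Khlong Hoi Khong,38,1.4,2734
district,female,Muang Songkhla,161,14.5,1110
district,female,Sathing Phra,56,5.1,1110
district,female,Chana,77,6.9,1110
district,female,Na Thawi,41,3.7,1110
district,female,Thepha,42,3.8,1110
district,female,Saba Yoi,21,1.9,1110
district,female,Ranot,71,6.4,1110
district,female,Krasae Sin,14,1.3,1110
district,female,Rattaphum,46,4.1,1110
district,female,Sadao,79,7.1,1110
district,female,Hat Yai,355,32.0,1110
district,female,Na Mom,23,2.1,1110
district,female,Khuan Niang,37,3.3,1110
district,female,Bang Klam,17,1.5,1110
district,female,Singhanakhon,55,4.9,1110
district,female,Khlong Hoi Khong,15,1.3,1110
period,male,1989-1993,272,10.0,2734
period,male,1994-1998,336,12.3,2734
period,male,1999-2003,434,15.9,2734
period,male,2004-2008,794,29.0,2734
period,male,2009-2013,898,32.8,2734
period,female,1989-1993,92,8.3,1110
period,female,1994-1998,130,11.7,1110
period,female,1999-2003,178,16.0,1110
period,female,2004-2008,257,23.2,1110
period,female,2009-2013,453,40.8,1110
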