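sex,period,class,count,pct
male,1989-1993,SCC,102,29.3
male,1989-1993,ADCA,90,25.9
male,1989-1993,NSCC_NOS,0,0.0
male,1989-1993,OTHER,52,14.9
male,1989-1993,UNKNOWN,104,29.9
male,1994-1998,SCC,97,29.9
male,1994-1998,ADCA,107,33.0
male,1994-1998,NSCC_NOS,1,0.3
male,1994-1998,OTHER,44,13.6
male,1994-1998,UNKNOWN,75,23.2
male,1999-2003,SCC,136,26.5
male,1999-2003,ADCA,172,33.5
male,1999-2003,NSCC_NOS,25,4.9
male,1999-2003,OTHER,69,13.4
male,1999-2003,UNKNOWN,112,21.8
male,2004-2008,SCC,145,18.0
male,2004-2008,ADCA,266,33.0
male,2004-2008,NSCC_NOS,44,5.5
male,2004-2008,OTHER,72,8.9
male,2004-2008,UNKNOWN,280,34.7
male,2009-2013,SCC,105,14.2
male,2009-2013,ADCA,273,36.8
male,2009-2013,NSCC_NOS,61,8.2
male,2009-2013,OTHER,73,9.9
male,2009-2013,UNKNOWN,229,30.9
female,1989-1993,SCC,21,18.4
female,1989-1993,ADCA,48,42.1
female,1989-1993,NSCC_NOS,0,0.0
female,1989-1993,OTHER,9,7.9
female,1989-1993,UNKNOWN,36,31.6
female,1994-1998,SCC,16,11.4
female,1994-1998,ADCA,72,50.7
female,1994-1998,NSCC_NOS,0,0.0
female,1994-1998,OTHER,17,12.1
female,1994-1998,UNKNOWN,36,25.7
female,1999-2003,SCC,25,13.6
female,1999-2003,ADCA,92,50.0
female,1999-2003,NSCC_NOS,6,3.3
female,1999-2003,OTHER,7,3.8
female,1999-2003,UNKNOWN,54,29.4
female,2004-2008,SCC,17,5.6
female,2004-2008,ADCA,161,53.3
female,2004-2008,NSCC_NOS,17,5.6
female,2004-2008,OTHER,8,2.7
female,2004-2008,UNKNOWN,99,32.8
female,2009-2013,SCC,14,3.8
female,2009-2013,ADCA,211,57.0
female,2009-2013,NSCC_NOS,18,4.9
female,2009-2013,OTHER,16,4.3
female,2009-2013,UNKNOWN,111,30.0
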