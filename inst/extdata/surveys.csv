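year,date,time,tide
2003,2003-08-02,1245-1430,Spring High
2003,2003-08-03,1400-1600,Spring High
2003,2003-08-04,1400-1600,Spring High
2003,2003-08-06,1645-1845,Neap High
2003,2003-08-09,0800-1000,Neap High
2003,2003-08-12,1000-1215,Spring High
2003,2003-08-13,1030-1245,Spring High
2005,2005-07-29,1630-1830,Neap High
2005,2005-07-30,1630-1845,Neap High
2005,2005-07-31,1715-1930,Neap High
2005,2005-08-01,1900-2045,Neap High
2005,2005-08-03,0845-1100,Neap High
2005,2005-08-05,1000-1215,Spring High
2005,2005-08-07,1145-1345,Spring High
2005,2005-08-10,1330-1515,Spring High
2005,2005-08-11,1415-1615,Spring High
2005,2005-08-13,1530-1730,Neap High
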