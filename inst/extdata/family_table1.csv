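person_id,sex,brca1,rnf43,age_last_contact,record_type,age,tumor_type,location,histology,size_min_mm,size_max_mm,count,lesion_background
001,F,Carrier,Carrier,,diagnosis,53,CRC,caecum,adenocarcinoma,,,,
001,F,Carrier,Carrier,,diagnosis,62,peritoneal,,,,,,
001,F,Carrier,Carrier,,diagnosis,63,ovarian,,,,,,
002,F,unknown,unknown,,diagnosis,58,CRC,colon,adenocarcinoma,,,,
005,F,unknown,unknown,,diagnosis,67,intestinal,,,,,,
006,M,unknown,unknown,,diagnosis,80,laryngeal,larynx,,,,,
009,F,Carrier,Carrier,,diagnosis,44,CRC,transverse colon,adenocarcinoma,,,,
010,F,Carrier,Carrier,,polyp,44,,ascending colon,tubular_adenoma,,,1,FALSE
010,F,Carrier,Carrier,,diagnosis,56,CRC,sigmoid colon,adenocarcinoma,,,,
010,F,Carrier,Carrier,,polyp,56,,sigmoid colon,SSL,15,15,1,TRUE
010,F,Carrier,Carrier,,polyp,56,,transverse colon,hyperplastic,10,10,1,FALSE
010,F,Carrier,Carrier,,polyp,59,,ascending colon,adenomatous,6,8,1,FALSE
010,F,Carrier,Carrier,,polyp,59,,ascending colon,SSL,6,8,1,FALSE
010,F,Carrier,Carrier,,polyp,59,,sigmoid colon,hyperplastic,6,8,2,FALSE
010,F,Carrier,Carrier,,polyp,62,,rectum,hyperplastic,5,8,1,FALSE
011,F,Wildtype,Wildtype,61,none,,,,,,,,
012,M,Wildtype,Wildtype,60,none,,,,,,,,
013,F,unknown,unknown,,diagnosis,,uterine,,,,,,
014,M,Carrier,Carrier,,diagnosis,56,CRC,transverse colon,adenocarcinoma,,,,
014,M,Carrier,Carrier,,diagnosis,71,prostate,prostate,,,,,
016,M,Wildtype,Wildtype,,diagnosis,46,lymphoma,right neck lymph node,follicular lymphoma,,,,
017,F,Wildtype,Wildtype,50,none,,,,,,,,
018,M,Carrier,Wildtype,,diagnosis,57,laryngeal,larynx,squamous cell carcinoma,,,,
018,M,Carrier,Wildtype,,diagnosis,58,prostate,prostate,adenocarcinoma,,,,
021,F,Wildtype,Wildtype,,diagnosis,34,cervical,uterus cervix,,,,,
023,M,Wildtype,Wildtype,54,none,,,,,,,,
024,F,Wildtype,Wildtype,84,none,,,,,,,,
025,F,Obligate carrier,Obligate carrier,,diagnosis,34,breast,,,,,,
026,M,Carrier,Carrier,58,none,,,,,,,,
027,M,Carrier,Carrier,,diagnosis,57,metastatic_unknown_primary,liver,,,,,
028,F,Wildtype,Carrier,54,none,,,,,,,,
030,M,Wildtype,Wildtype,82,none,,,,,,,,
034,F,unknown,unknown,,diagnosis,,intestinal,,,,,,
036,F,Wildtype,Wildtype,,diagnosis,50,endometrial,uterus,adenocarcinoma,,,,
042,F,Wildtype,Wildtype,44,none,,,,,,,,
045,M,unknown,unknown,,diagnosis,,lung,,,,,,
047,F,unknown,unknown,,diagnosis,,kidney,,,,,,
055,M,Wildtype,not_tested,35,none,,,,,,,,
056,F,Carrier,not_tested,,diagnosis,,breast,,,,,,
100,F,Carrier,not_tested,28,none,,,,,,,,
101,F,Wildtype,not_tested,26,none,,,,,,,,
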