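signal_id,source,scan_period,status,discard_reason,signature,dscs,source_ref
SIG00001,clinicaltrials,1,selected,,2.3.2.1,B.T.2.3,
SIG00002,epo,1,selected,,2.3.2.1,B.T.2.3,
SIG00003,epo,3,selected,,2.3.2.1,B.T.2.3,
SIG00004,epo,1,selected,,2.3.2.2,B.T.2.3,
SIG00005,epo,1,selected,,2.3.2.1,B.T.2.3,
SIG00006,scopus,2,selected,,2.3.3.1,B.T.2.3,
SIG00007,epo,3,selected,,2.3.2.2,B.T.2.3,
SIG00008,epo,1,selected,,2.1.2.0,E.T.2.1,
SIG00009,epo,3,selected,,2.1.2.1,E.T.2.1,
SIG00010,epo,2,selected,,2.1.1.0,E.T.2.1,
SIG00011,epo,1,selected,,2.1.1.1,E.T.2.1,
SIG00012,epo,2,selected,,2.3.3s.1,C.T.2.3,
SIG00013,clinicaltrials,1,selected,,2.3.3.1,C.T.2.3,
SIG00014,epo,1,selected,,2.3.2.1,C.T.2.3,
SIG00015,epo,1,selected,,2.3.3s.1,C.T.2.3,
SIG00016,scopus,1,selected,,1.2.3s.1,AA.T.1.2,
SIG00017,clinicaltrials,3,selected,,1.2.2s.0,AA.T.1.2,
SIG00018,epo,3,selected,,1.2.1.2,AA.T.1.2,
SIG00019,epo,3,selected,,1.2.0.1,BA.T.1.2,
SIG00020,epo,1,selected,,1.2.1s.1,BA.T.1.2,
SIG00021,epo,1,selected,,2.2.1.1,CA.T.2.2,
SIG00022,clinicaltrials,1,selected,,2.2.0.0,CA.T.2.2,
SIG00023,epo,1,selected,,1.2.1.1,DA.T.1.2,
SIG00024,epo,2,selected,,1.2.1.0,DA.T.1.2,
SIG00025,clinicaltrials,1,selected,,2.3.0.1,EA.T.2.3,
SIG00026,scopus,1,selected,,2.3.2.1,EA.T.2.3,
SIG00027,clinicaltrials,1,selected,,2.1.0.0,FA.T.2.1,
SIG00028,epo,1,selected,,2.1.2.0,FA.T.2.1,
SIG00029,scopus,1,selected,,2.1.2.1,GA.T.2.1,
SIG00030,epo,1,selected,,2.1.2.1,GA.T.2.1,
SIG00031,epo,2,selected,,2.1.2.0,HA.T.2.1,
SIG00032,clinicaltrials,1,selected,,2.1.2.2,HA.T.2.1,
SIG00033,clinicaltrials,1,selected,,2.1.3.0,IA.T.2.1,
SIG00034,epo,3,selected,,2.1.2s.0,IA.T.2.1,
SIG00035,clinicaltrials,1,selected,,1.1.0.0,JA.T.1.1,
SIG00036,scopus,3,selected,,1.1.0.2,JA.T.1.1,
SIG00037,clinicaltrials,1,selected,,2.2.3.0,KA.T.2.2,
SIG00038,epo,2,selected,,2.2.1.0,KA.T.2.2,
SIG00039,clinicaltrials,1,selected,,2.2.2s.0,LA.T.2.2,
SIG00040,epo,1,selected,,2.2.3.1,LA.T.2.2,
SIG00041,epo,1,selected,,2.1.0.1,MA.T.2.1,
SIG00042,clinicaltrials,2,selected,,2.1.1.0,MA.T.2.1,
SIG00043,epo,1,selected,,2.3.1.1,NA.T.2.3,
SIG00044,epo,1,selected,,2.3.1s.1,NA.T.2.3,
SIG00045,epo,1,selected,,2.1.3.0,OA.T.2.1,
SIG00046,scopus,2,selected,,1.2.2.1,PA.T.1.2,
SIG00047,epo,2,selected,,1.1.2.2,QA.T.1.1,
SIG00048,epo,3,selected,,1.2.3.0,RA.T.1.2,
SIG00049,clinicaltrials,1,selected,,2.1.3s.0,SA.T.2.1,
SIG00050,scopus,1,selected,,1.2.3.1,TA.T.1.2,
SIG00051,epo,1,selected,,2.3.1s.1,UA.T.2.3,
SIG00052,epo,3,selected,,1.1.0.0,VA.T.1.1,
SIG00053,clinicaltrials,1,selected,,2.3.1.1,WA.T.2.3,
SIG00054,epo,1,selected,,1.1.1.0,AB.T.1.1,
SIG00055,clinicaltrials,1,selected,,2.3.2.1,BB.T.2.3,
SIG00056,epo,1,selected,,2.1.2.1,CB.T.2.1,
SIG00057,epo,1,selected,,1.1.0.1,DB.T.1.1,
SIG00058,clinicaltrials,1,selected,,2.2.2.1,EB.T.2.2,
SIG00059,epo,1,selected,,2.(1.2.3).1.1,F.T.2.1;A.T.2.2;P.T.2.3,
SIG00060,epo,2,selected,,1.1.(2.3).1,K.T.1.1;XA.T.2.1;E.T.2.2,
SIG00061,scopus,1,discarded,outside the selected timeframe,,,
SIG00062,scopus,1,discarded,outside the selected timeframe,,,
SIG00063,scopus,1,discarded,not describing an NHP in particular,,,
SIG00064,scopus,1,discarded,outside the selected timeframe,,,
SIG00065,scopus,1,discarded,duplicated record,,,
SIG00066,scopus,1,discarded,not describing an NHP in particular,,,
SIG00067,scopus,1,discarded,not describing an NHP in particular,,,
SIG00068,scopus,1,discarded,outside the selected timeframe,,,
SIG00069,scopus,1,discarded,not describing an NHP in particular,,,
SIG00070,scopus,1,discarded,not describing an NHP in particular,,,
SIG00071,scopus,1,discarded,not describing an NHP in particular,,,
SIG00072,scopus,1,discarded,not describing an NHP in particular,,,
SIG00073,scopus,2,discarded,not describing an NHP in particular,,,
SIG00074,scopus,2,discarded,duplicated record,,,
SIG00075,scopus,3,discarded,duplicated record,,,
SIG00076,scopus,3,discarded,not describing an NHP in particular,,,
SIG00077,epo,1,discarded,not describing an NHP in particular,,,
SIG00078,epo,1,discarded,not describing an NHP in particular,,,
SIG00079,epo,1,discarded,source document not available,,,
SIG00080,epo,1,discarded,not describing an NHP in particular,,,
SIG00081,epo,1,discarded,not describing an NHP in particular,,,
SIG00082,epo,1,discarded,not describing an NHP in particular,,,
SIG00083,epo,2,discarded,not describing an NHP in particular,,,
SIG00084,epo,2,discarded,source document not available,,,
SIG00085,epo,3,discarded,not describing an NHP in particular,,,
SIG00086,epo,3,discarded,not describing an NHP in particular,,,
SIG00087,clinicaltrials,1,discarded,outside the selected timeframe,,,
SIG00088,clinicaltrials,1,discarded,not describing an NHP in particular,,,
SIG00089,clinicaltrials,1,discarded,duplicated record,,,
SIG00090,clinicaltrials,1,discarded,not describing an NHP in particular,,,
SIG00091,clinicaltrials,1,discarded,outside the selected timeframe,,,
SIG00092,clinicaltrials,1,discarded,not describing an NHP in particular,,,
SIG00093,clinicaltrials,1,discarded,not at the nano-scale,,,
SIG00094,clinicaltrials,1,discarded,not describing an NHP in particular,,,
SIG00095,clinicaltrials,1,discarded,not describing an NHP in particular,,,
SIG00096,clinicaltrials,1,discarded,not describing an NHP in particular,,,
SIG00097,clinicaltrials,1,discarded,outside the selected timeframe,,,
SIG00098,clinicaltrials,1,discarded,not describing an NHP in particular,,,
SIG00099,clinicaltrials,2,discarded,not describing an NHP in particular,,,
SIG00100,clinicaltrials,3,discarded,outside the selected timeframe,,,
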