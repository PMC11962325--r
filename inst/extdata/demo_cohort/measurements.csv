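"patient_id","analyte","time","value"
"DIP","scr","2020-03-01 08:00:00",0.9
"DIP","scr","2020-03-01 16:00:00",0.9
"DIP","scr","2020-03-02 14:00:00",0.6
"DIP","scr","2020-03-03 08:00:00",0.9
"DIP","scr","2020-03-04 08:00:00",0.9
"LOWB","scr","2020-03-01 08:00:00",0.5
"LOWB","scr","2020-03-02 08:00:00",0.48
"LOWB","scr","2020-03-03 08:00:00",0.5
"LOWB","scr","2020-03-04 08:00:00",0.76
"LOWB","scr","2020-03-05 08:00:00",0.5
"LOWB","scr","2020-03-06 08:00:00",0.49
"DAY1","scr","2020-03-01 08:00:00",0.8
"DAY1","scr","2020-03-01 13:00:00",0.9
"DAY1","scr","2020-03-01 19:00:00",1.2
"DAY1","scr","2020-03-02 08:00:00",1.3
"DAY1","scr","2020-03-03 08:00:00",1.1
"RECOV","scr","2020-03-01 08:00:00",0.8
"RECOV","scr","2020-03-02 08:00:00",0.8
"RECOV","scr","2020-03-03 08:00:00",0.8
"RECOV","scr","2020-03-04 08:00:00",0.8
"RECOV","scr","2020-03-05 08:00:00",1.4
"RECOV","scr","2020-03-06 08:00:00",1.4
"RECOV","scr","2020-03-07 08:00:00",1.35
"RECOV","scr","2020-03-08 08:00:00",1.3
"RECOV","scr","2020-03-09 08:00:00",1.25
"RECOV","scr","2020-03-10 08:00:00",0.9
"RECOV","scr","2020-03-11 08:00:00",0.8
"RECOV","scr","2020-03-12 08:00:00",0.8
"AKD","scr","2020-03-01 08:00:00",0.7
"AKD","scr","2020-03-02 08:00:00",0.7
"AKD","scr","2020-03-03 08:00:00",0.7
"AKD","scr","2020-03-04 08:00:00",0.7
"AKD","scr","2020-03-05 08:00:00",0.7
"AKD","scr","2020-03-06 08:00:00",1.3
"AKD","scr","2020-03-07 08:00:00",1.35
"AKD","scr","2020-03-08 08:00:00",1.3
"AKD","scr","2020-03-09 08:00:00",1.3
"AKD","scr","2020-03-10 08:00:00",1.25
"AKD","scr","2020-03-11 08:00:00",1.3
"AKD","scr","2020-03-12 08:00:00",1.3
"AKD","scr","2020-03-13 08:00:00",1.25
"AKD","scr","2020-03-14 08:00:00",1.2
"INDET","scr","2020-03-01 08:00:00",0.8
"INDET","scr","2020-03-02 08:00:00",0.8
"INDET","scr","2020-03-03 08:00:00",0.8
"INDET","scr","2020-03-04 08:00:00",0.8
"INDET","scr","2020-03-05 08:00:00",1.3
"TWOSCR","scr","2020-03-01 08:00:00",0.9
"TWOSCR","scr","2020-03-03 08:00:00",0.95
"CTRL","scr","2020-03-01 08:00:00",0.7
"CTRL","scr","2020-03-02 08:00:00",0.72
"CTRL","scr","2020-03-04 08:00:00",0.7
"CTRL","scr","2020-03-06 08:00:00",0.71
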