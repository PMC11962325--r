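"patient_id","class","onset_day","recovery_day","baseline","sex","age"
"DIP","transient_dip",NA,NA,0.9,"male",55
"LOWB","transient_low",NA,NA,0.49,"female",40
"DAY1","day1_aki",1,NA,0.8,"male",60
"RECOV","aki_recovered",5,5,0.8,"male",50
"AKD","aki_akd",6,NA,0.7,"male",65
"INDET","aki_indeterminate",5,NA,0.8,"female",58
"TWOSCR","too_few_scr",NA,NA,0.9,"male",45
"CTRL","no_aki",NA,NA,0.7,"female",35
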