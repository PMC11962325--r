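"patient_id","age","sex","admit_time","discharge_time","height","weight"
"DIP",55,"male","2020-03-01 07:00:00","2020-03-08 18:00:00",170,65
"LOWB",40,"female","2020-03-01 07:00:00","2020-03-08 18:00:00",170,65
"DAY1",60,"male","2020-03-01 07:00:00","2020-03-08 18:00:00",170,65
"RECOV",50,"male","2020-03-01 07:00:00","2020-03-14 18:00:00",170,65
"AKD",65,"male","2020-03-01 07:00:00","2020-03-16 18:00:00",170,65
"INDET",58,"female","2020-03-01 07:00:00","2020-03-09 18:00:00",170,65
"TWOSCR",45,"male","2020-03-01 07:00:00","2020-03-06 18:00:00",170,65
"CTRL",35,"female","2020-03-01 07:00:00","2020-03-07 18:00:00",170,65
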