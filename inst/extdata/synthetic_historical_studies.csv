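"study_id","treated_events","treated_n","control_events","control_n"
"study01",58,283,22,109
"study02",40,238,20,70
"study03",21,95,71,264
"study04",34,167,41,134
"study05",43,195,27,83
"study06",25,103,33,105
"study07",44,241,66,252
"study08",19,102,57,271
"study09",20,111,46,154
"study10",22,101,22,96
"study11",7,68,49,226
"study12",50,154,55,208
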