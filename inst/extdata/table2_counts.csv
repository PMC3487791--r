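"cohort","timepoint_months","change_1d","change_3d","count"
"training",3,"DECREASE","DECREASE",12
"training",3,"DECREASE","NO_CHANGE",1
"training",3,"DECREASE","INCREASE",1
"training",3,"NO_CHANGE","DECREASE",16
"training",3,"NO_CHANGE","NO_CHANGE",11
"training",3,"NO_CHANGE","INCREASE",6
"training",3,"INCREASE","DECREASE",0
"training",3,"INCREASE","NO_CHANGE",1
"training",3,"INCREASE","INCREASE",2
"training",6,"DECREASE","DECREASE",17
"training",6,"DECREASE","NO_CHANGE",1
"training",6,"DECREASE","INCREASE",0
"training",6,"NO_CHANGE","DECREASE",18
"training",6,"NO_CHANGE","NO_CHANGE",10
"training",6,"NO_CHANGE","INCREASE",2
"training",6,"INCREASE","DECREASE",0
"training",6,"INCREASE","NO_CHANGE",0
"training",6,"INCREASE","INCREASE",6
"training",12,"DECREASE","DECREASE",23
"training",12,"DECREASE","NO_CHANGE",0
"training",12,"DECREASE","INCREASE",0
"training",12,"NO_CHANGE","DECREASE",5
"training",12,"NO_CHANGE","NO_CHANGE",7
"training",12,"NO_CHANGE","INCREASE",4
"training",12,"INCREASE","DECREASE",0
"training",12,"INCREASE","NO_CHANGE",0
"training",12,"INCREASE","INCREASE",7
"validation",3,"DECREASE","DECREASE",7
"validation",3,"DECREASE","NO_CHANGE",0
"validation",3,"DECREASE","INCREASE",0
"validation",3,"NO_CHANGE","DECREASE",14
"validation",3,"NO_CHANGE","NO_CHANGE",1
"validation",3,"NO_CHANGE","INCREASE",3
"validation",3,"INCREASE","DECREASE",0
"validation",3,"INCREASE","NO_CHANGE",0
"validation",3,"INCREASE","INCREASE",3
"validation",6,"DECREASE","DECREASE",12
"validation",6,"DECREASE","NO_CHANGE",1
"validation",6,"DECREASE","INCREASE",0
"validation",6,"NO_CHANGE","DECREASE",6
"validation",6,"NO_CHANGE","NO_CHANGE",3
"validation",6,"NO_CHANGE","INCREASE",1
"validation",6,"INCREASE","DECREASE",0
"validation",6,"INCREASE","NO_CHANGE",0
"validation",6,"INCREASE","INCREASE",4
"validation",12,"DECREASE","DECREASE",15
"validation",12,"DECREASE","NO_CHANGE",0
"validation",12,"DECREASE","INCREASE",0
"validation",12,"NO_CHANGE","DECREASE",1
"validation",12,"NO_CHANGE","NO_CHANGE",3
"validation",12,"NO_CHANGE","INCREASE",2
"validation",12,"INCREASE","DECREASE",0
"validation",12,"INCREASE","NO_CHANGE",0
"validation",12,"INCREASE","INCREASE",4
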