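"cohort","timepoint_months","criteria","recist","other","count"
"training",3,"SPHERE","PR","PR",4
"training",3,"SPHERE","PR","SD",0
"training",3,"SPHERE","PR","PD",0
"training",3,"SPHERE","SD","PR",6
"training",3,"SPHERE","SD","SD",34
"training",3,"SPHERE","SD","PD",1
"training",3,"SPHERE","PD","PR",0
"training",3,"SPHERE","PD","SD",0
"training",3,"SPHERE","PD","PD",5
"training",3,"ELLIPSOID","PR","PR",4
"training",3,"ELLIPSOID","PR","SD",0
"training",3,"ELLIPSOID","PR","PD",0
"training",3,"ELLIPSOID","SD","PR",22
"training",3,"ELLIPSOID","SD","SD",15
"training",3,"ELLIPSOID","SD","PD",4
"training",3,"ELLIPSOID","PD","PR",0
"training",3,"ELLIPSOID","PD","SD",0
"training",3,"ELLIPSOID","PD","PD",5
"training",3,"CHOI","PR","PR",3
"training",3,"CHOI","PR","SD",1
"training",3,"CHOI","PR","PD",0
"training",3,"CHOI","SD","PR",23
"training",3,"CHOI","SD","SD",11
"training",3,"CHOI","SD","PD",4
"training",3,"CHOI","PD","PR",0
"training",3,"CHOI","PD","SD",1
"training",3,"CHOI","PD","PD",2
"training",6,"SPHERE","PR","PR",6
"training",6,"SPHERE","PR","SD",0
"training",6,"SPHERE","PR","PD",0
"training",6,"SPHERE","SD","PR",10
"training",6,"SPHERE","SD","SD",30
"training",6,"SPHERE","SD","PD",0
"training",6,"SPHERE","PD","PR",0
"training",6,"SPHERE","PD","SD",0
"training",6,"SPHERE","PD","PD",8
"training",6,"ELLIPSOID","PR","PR",6
"training",6,"ELLIPSOID","PR","SD",0
"training",6,"ELLIPSOID","PR","PD",0
"training",6,"ELLIPSOID","SD","PR",24
"training",6,"ELLIPSOID","SD","SD",13
"training",6,"ELLIPSOID","SD","PD",3
"training",6,"ELLIPSOID","PD","PR",0
"training",6,"ELLIPSOID","PD","SD",0
"training",6,"ELLIPSOID","PD","PD",8
"training",6,"CHOI","PR","PR",5
"training",6,"CHOI","PR","SD",0
"training",6,"CHOI","PR","PD",0
"training",6,"CHOI","SD","PR",23
"training",6,"CHOI","SD","SD",14
"training",6,"CHOI","SD","PD",1
"training",6,"CHOI","PD","PR",1
"training",6,"CHOI","PD","SD",1
"training",6,"CHOI","PD","PD",5
"training",12,"SPHERE","PR","PR",12
"training",12,"SPHERE","PR","SD",0
"training",12,"SPHERE","PR","PD",0
"training",12,"SPHERE","SD","PR",3
"training",12,"SPHERE","SD","SD",17
"training",12,"SPHERE","SD","PD",3
"training",12,"SPHERE","PD","PR",0
"training",12,"SPHERE","PD","SD",1
"training",12,"SPHERE","PD","PD",10
"training",12,"ELLIPSOID","PR","PR",12
"training",12,"ELLIPSOID","PR","SD",0
"training",12,"ELLIPSOID","PR","PD",0
"training",12,"ELLIPSOID","SD","PR",13
"training",12,"ELLIPSOID","SD","SD",5
"training",12,"ELLIPSOID","SD","PD",5
"training",12,"ELLIPSOID","PD","PR",0
"training",12,"ELLIPSOID","PD","SD",0
"training",12,"ELLIPSOID","PD","PD",11
"training",12,"CHOI","PR","PR",10
"training",12,"CHOI","PR","SD",0
"training",12,"CHOI","PR","PD",0
"training",12,"CHOI","SD","PR",13
"training",12,"CHOI","SD","SD",7
"training",12,"CHOI","SD","PD",2
"training",12,"CHOI","PD","PR",1
"training",12,"CHOI","PD","SD",1
"training",12,"CHOI","PD","PD",8
"validation",3,"SPHERE","PR","PR",1
"validation",3,"SPHERE","PR","SD",0
"validation",3,"SPHERE","PR","PD",0
"validation",3,"SPHERE","SD","PR",0
"validation",3,"SPHERE","SD","SD",24
"validation",3,"SPHERE","SD","PD",0
"validation",3,"SPHERE","PD","PR",0
"validation",3,"SPHERE","PD","SD",0
"validation",3,"SPHERE","PD","PD",3
"validation",3,"ELLIPSOID","PR","PR",1
"validation",3,"ELLIPSOID","PR","SD",0
"validation",3,"ELLIPSOID","PR","PD",0
"validation",3,"ELLIPSOID","SD","PR",16
"validation",3,"ELLIPSOID","SD","SD",5
"validation",3,"ELLIPSOID","SD","PD",3
"validation",3,"ELLIPSOID","PD","PR",0
"validation",3,"ELLIPSOID","PD","SD",0
"validation",3,"ELLIPSOID","PD","PD",3
"validation",3,"CHOI","PR","PR",1
"validation",3,"CHOI","PR","SD",0
"validation",3,"CHOI","PR","PD",0
"validation",3,"CHOI","SD","PR",21
"validation",3,"CHOI","SD","SD",2
"validation",3,"CHOI","SD","PD",1
"validation",3,"CHOI","PD","PR",2
"validation",3,"CHOI","PD","SD",0
"validation",3,"CHOI","PD","PD",1
"validation",6,"SPHERE","PR","PR",5
"validation",6,"SPHERE","PR","SD",1
"validation",6,"SPHERE","PR","PD",0
"validation",6,"SPHERE","SD","PR",3
"validation",6,"SPHERE","SD","SD",14
"validation",6,"SPHERE","SD","PD",0
"validation",6,"SPHERE","PD","PR",0
"validation",6,"SPHERE","PD","SD",0
"validation",6,"SPHERE","PD","PD",4
"validation",6,"ELLIPSOID","PR","PR",6
"validation",6,"ELLIPSOID","PR","SD",0
"validation",6,"ELLIPSOID","PR","PD",0
"validation",6,"ELLIPSOID","SD","PR",11
"validation",6,"ELLIPSOID","SD","SD",5
"validation",6,"ELLIPSOID","SD","PD",1
"validation",6,"ELLIPSOID","PD","PR",0
"validation",6,"ELLIPSOID","PD","SD",0
"validation",6,"ELLIPSOID","PD","PD",4
"validation",6,"CHOI","PR","PR",6
"validation",6,"CHOI","PR","SD",0
"validation",6,"CHOI","PR","PD",0
"validation",6,"CHOI","SD","PR",15
"validation",6,"CHOI","SD","SD",2
"validation",6,"CHOI","SD","PD",0
"validation",6,"CHOI","PD","PR",3
"validation",6,"CHOI","PD","SD",0
"validation",6,"CHOI","PD","PD",1
"validation",12,"SPHERE","PR","PR",9
"validation",12,"SPHERE","PR","SD",0
"validation",12,"SPHERE","PR","PD",0
"validation",12,"SPHERE","SD","PR",1
"validation",12,"SPHERE","SD","SD",9
"validation",12,"SPHERE","SD","PD",1
"validation",12,"SPHERE","PD","PR",0
"validation",12,"SPHERE","PD","SD",0
"validation",12,"SPHERE","PD","PD",5
"validation",12,"ELLIPSOID","PR","PR",9
"validation",12,"ELLIPSOID","PR","SD",0
"validation",12,"ELLIPSOID","PR","PD",0
"validation",12,"ELLIPSOID","SD","PR",5
"validation",12,"ELLIPSOID","SD","SD",4
"validation",12,"ELLIPSOID","SD","PD",2
"validation",12,"ELLIPSOID","PD","PR",0
"validation",12,"ELLIPSOID","PD","SD",0
"validation",12,"ELLIPSOID","PD","PD",5
"validation",12,"CHOI","PR","PR",9
"validation",12,"CHOI","PR","SD",0
"validation",12,"CHOI","PR","PD",0
"validation",12,"CHOI","SD","PR",9
"validation",12,"CHOI","SD","SD",1
"validation",12,"CHOI","SD","PD",1
"validation",12,"CHOI","PD","PR",3
"validation",12,"CHOI","PD","SD",0
"validation",12,"CHOI","PD","PD",2
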