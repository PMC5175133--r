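"sample_id","group","gene","ct_target","ct_reference"
"control1","control","DEPDC1B",24.327315615371,20
"control2","control","DEPDC1B",26.1074874747829,20
"control3","control","DEPDC1B",23.9956065098979,20
"control4","control","DEPDC1B",25.0561142131419,20
"control5","control","DEPDC1B",26.3691526981619,20
"control6","control","DEPDC1B",24.5176736148363,20
"control7","control","DEPDC1B",24.6222668918664,20
"control8","control","DEPDC1B",24.4917029499806,20
"case1","case","DEPDC1B",22.2713810921071,20
"case2","case","DEPDC1B",22.6104865798431,20
"case3","case","DEPDC1B",23.4821042750828,20
"case4","case","DEPDC1B",21.8585764362777,20
"case5","case","DEPDC1B",21.6356859199781,20
"case6","case","DEPDC1B",22.3739725151145,20
"case7","case","DEPDC1B",21.6425919680977,20
"case8","case","DEPDC1B",22.3888110875601,20
"control1","control","DEPDC7",24.5221495242297,20
"control2","control","DEPDC7",23.2528265919267,20
"control3","control","DEPDC7",25.1926538047494,20
"control4","control","DEPDC7",24.7925156746126,20
"control5","control","DEPDC7",25.7204095562666,20
"control6","control","DEPDC7",25.7534955150942,20
"control7","control","DEPDC7",26.1743695227358,20
"control8","control","DEPDC7",25.5654088716463,20
"case1","case","DEPDC7",23.1552071442097,20
"case2","case","DEPDC7",22.265214521038,20
"case3","case","DEPDC7",23.6348712579888,20
"case4","case","DEPDC7",23.6990190619252,20
"case5","case","DEPDC7",21.9743343244115,20
"case6","case","DEPDC7",21.8177636479984,20
"case7","case","DEPDC7",22.7527320306892,20
"case8","case","DEPDC7",23.3877553341271,20
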