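"scenario","year","n","baseline_total","scenario_total","incremental","per_patient","arm_id","role","share","arm_cost"
"scenario1",2024,173,31124763,29890060,-1234703,-7137,"abma","intervention",0.2,4990249
"scenario1",2024,173,31124763,29890060,-1234703,-7137,"cdk_mix","comparator_mix",0.8,24899810
"scenario1",2025,182,32681001,30736344,-1944658,-10685,"abma","intervention",0.3,7859643
"scenario1",2025,182,32681001,30736344,-1944658,-10685,"cdk_mix","comparator_mix",0.7,22876701
"scenario1",2026,191,34363178,31636839,-2726339,-14274,"abma","intervention",0.4,11018932
"scenario1",2026,191,34363178,31636839,-2726339,-14274,"cdk_mix","comparator_mix",0.6,20617907
"scenario1",2027,201,36081336,32503017,-3578320,-17803,"abma","intervention",0.5,14462348
"scenario1",2027,201,36081336,32503017,-3578320,-17803,"cdk_mix","comparator_mix",0.5,18040668
"scenario1",2028,211,37961416,33443687,-4517729,-21411,"abma","intervention",0.6,18259121
"scenario1",2028,211,37961416,33443687,-4517729,-21411,"cdk_mix","comparator_mix",0.4,15184566
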