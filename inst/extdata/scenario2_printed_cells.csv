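"scenario","year","n","baseline_total","scenario_total","incremental","per_patient","arm_id","role","share","arm_cost"
"scenario2",2024,173,27102920,27893201,790281,4568,"abma_ribo","intervention",0.3,8921157
"scenario2",2024,173,27102920,27893201,790281,4568,"plbo_mix","comparator_mix",0.7,18972044
"scenario2",2025,182,28458066,29564460,1106393,6079,"abma_ribo","intervention",0.4,12489620
"scenario2",2025,182,28458066,29564460,1106393,6079,"plbo_mix","comparator_mix",0.6,17074840
"scenario2",2026,191,29922877,31377055,1454178,7613,"abma_ribo","intervention",0.5,16415617
"scenario2",2026,191,29922877,31377055,1454178,7613,"plbo_mix","comparator_mix",0.5,14961439
"scenario2",2027,201,31419021,33403974,1984953,9875,"abma_ribo","intervention",0.65,22407317
"scenario2",2027,201,31419021,33403974,1984953,9875,"plbo_mix","comparator_mix",0.35,10996657
"scenario2",2028,211,33056163,35626479,2570316,12182,"abma_ribo","intervention",0.8,29015247
"scenario2",2028,211,33056163,35626479,2570316,12182,"plbo_mix","comparator_mix",0.2,6611233
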