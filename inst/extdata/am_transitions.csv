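variant_name,q1_mz,q3_mz,rt_min,sulfated
ARC-1,1226,834,3.89,FALSE
ARC-2,1266,754,3.03,TRUE
ARC-3,1358,932,2.90,FALSE
ARC-4,1398,886,2.93,TRUE
ARC-5,1426,1034,3.87,FALSE
ARC-6,1446,928,3.20,TRUE
ARC-7,1506,1080,4.35,FALSE
ARC-8,1608,1062,3.26,TRUE
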