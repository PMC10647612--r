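analyte,formula,reference_rt_min,precursor_mz,quantifier_mz,quantifier_ce,qualifier1_mz,qualifier1_ce,qualifier2_mz,qualifier2_ce,rf_lens
Rebaudioside A,C44H70O23,4.856,965.5,803.45,27.87,641.36,55,317.29,55,280
Rebaudioside B,C38H60O18,6.347,803.458,641.29,47.42,413.08,54.07,317.17,53.65,280
Rebaudioside C,C44H70O22,5.214,949.508,787.38,32.2,641.29,55,479.24,55,280
Rebaudioside D,C50H80O28,4.139,1127.558,803.35,51.93,641.32,55,623.30,55,280
Rebaudioside F,C43H68O22,5.113,935.4,773.35,26.9,611.292,55,641.321,55,280
Rubusoside,C32H50O13,5.693,641.348,478.92,14.14,521.45,23.07,317.15,46.95,226
Dulcoside A,C38H60O17,5.303,787.458,625.45,18.1,479.29,55,317.25,55,272
Stevioside,C38H60O18,4.895,803.458,641.39,19.66,479.22,55,317.34,55,257
Steviolbioside,C32H50O13,6.478,641.448,479.17,42.32,461.29,48.39,317.37,42.49,280
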