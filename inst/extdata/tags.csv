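tag_id,species,sex,fl_tag_mm,date_tagged,quality
L2881,R. terraenovae,male,776,,measured
L4774,R. terraenovae,female,815,,measured
L5173,R. terraenovae,male,737,,measured
L5242,R. terraenovae,male,802,,measured
L7250,R. terraenovae,male,810,,measured
L2910,C. acronotus,male,876,,measured
L1515,C. acronotus,female,878,,measured
L3384,C. acronotus,male,1020,,measured
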