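species,tag_id,initial_fl_mm,recapture_fl_mm,growth_mm,days_at_liberty,years_at_liberty,sex,age_tag_bt,age_recap_bt,age_direct
R. terraenovae,L2881,776,828,52,5098,14.0,male,5.2,19.2,
R. terraenovae,L4774,815,883,68,3237,8.9,female,10.1,19.0,
R. terraenovae,L5173,737,,,2937,8.0,male,3.8,11.8,
R. terraenovae,L5242,802,830,28,4438,12.1,male,7.7,19.8,18.5
R. terraenovae,L7250,810,838,28,2806,7.7,male,10.3,18.0,
C. acronotus,L2910,876,960,84,4352,11.9,male,4.5,16.4,15.5
C. acronotus,L1515,878,1055,177,4678,12.8,female,4.2,17.0,14.5
C. acronotus,L3384,1020,,,3986,10.9,male,11.9,22.8,20.5
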