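tag_id,date_recaptured,days_at_liberty,fl_recap_mm,quality
L2881,,5098,828,angler_estimate
L4774,,3237,883,angler_estimate
L5173,,2937,,missing
L5242,,4438,830,measured
L7250,,2806,838,angler_estimate
L2910,,4352,960,measured
L1515,,4678,1055,measured
L3384,,3986,,missing
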