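tag_id,reader_id,count
L5242,1,20
L5242,2,20
L5242,3,20
L2910,1,17
L2910,2,17
L2910,3,17
L1515,1,16
L1515,2,16
L1515,3,16
L3384,1,22
L3384,2,22
L3384,3,22
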