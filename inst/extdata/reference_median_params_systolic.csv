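subject_id,base,incr,k,t1,t2
9901,112.0,13.9,0.25,4.30,24.43
9902,106.2,15.0,0.81,6.18,22.83
9903,82.1,22.0,0.30,5.00,22.47
9904,103.7,10.9,0.07,3.53,23.85
9905,107.6,15.1,0.65,5.14,21.38
9906,101.7,20.8,0.40,5.35,22.37
overall,104.0,15.6,0.33,4.83,22.99
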