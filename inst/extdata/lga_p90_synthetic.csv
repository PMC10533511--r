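ga_week,sex,p90_g
34,female,3199
34,male,3279
35,female,3299
35,male,3379
36,female,3399
36,male,3479
37,female,3499
37,male,3579
38,female,3599
38,male,3679
39,female,3699
39,male,3779
40,female,3799
40,male,3879
41,female,3899
41,male,3979
42,female,3980
42,male,3980
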