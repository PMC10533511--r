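ga_days,median_mm
98,84.78
105,94.125
112,103.48
119,112.845
126,122.22
133,131.605
140,141
147,150.405
154,159.82
161,169.245
168,178.68
175,188.125
182,197.58
189,207.045
196,216.52
203,226.005
210,235.5
217,245.005
224,254.52
231,264.045
238,273.58
245,283.125
252,292.68
259,302.245
266,311.82
273,321.405
280,331
287,340.605
294,350.22
301,359.845
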