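ga_days,median_mm
98,27.76
105,31.5
112,35.16
119,38.74
126,42.24
133,45.66
140,49
147,52.26
154,55.44
161,58.54
168,61.56
175,64.5
182,67.36
189,70.14
196,72.84
203,75.46
210,78
217,80.46
224,82.84
231,85.14
238,87.36
245,89.5
252,91.56
259,93.54
266,95.44
273,97.26
280,99
287,100.66
294,102.24
301,103.74
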