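ga_days,median_mm
98,13.706
105,16.163
112,18.616
119,21.067
126,23.514
133,25.959
140,28.4
147,30.838
154,33.274
161,35.706
168,38.136
175,40.562
182,42.986
189,45.407
196,47.824
203,50.239
210,52.65
217,55.059
224,57.464
231,59.867
238,62.266
245,64.662
252,67.056
259,69.446
266,71.834
273,74.219
280,76.6
287,78.978
294,81.354
301,83.726
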