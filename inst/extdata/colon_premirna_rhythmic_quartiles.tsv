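quartile_band	feature_id
75-100	mir-30d
75-100	mir-7a-2
75-100	mir-7a-1
75-100	mir-150
75-100	mir-128-1
75-100	mir-128-2
75-100	mir-139
75-100	let-7g
75-100	mir-148b
75-100	mir-148a
50-75	mir-185
50-75	mir-425
50-75	mir-15b
50-75	mir-363
50-75	mir-129-1
50-75	mir-129-2
25-50	mir-20b
25-50	mir-153
25-50	mir-219a-1
25-50	mir-877
0-25	mir-3572
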