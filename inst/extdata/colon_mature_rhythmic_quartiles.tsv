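quartile_band	feature_id
75-100	miR-30d-5p
75-100	miR-7a-5p
75-100	miR-185-5p
75-100	miR-425-5p
75-100	miR-150-5p
75-100	miR-128-3p
75-100	miR-455-5p
75-100	miR-129-5p
75-100	miR-139-5p
75-100	miR-24-2-5p
75-100	let-7g-5p
75-100	miR-148b-3p
75-100	miR-148a-3p
75-100	miR-142-3p
50-75	miR-26b-3p
50-75	miR-363-3p
50-75	miR-15b-5p
50-75	miR-3068-3p
50-75	miR-9a-3p
50-75	miR-130a-3p
50-75	miR-3590-5p
50-75	miR-342-5p
25-50	miR-18a-5p
25-50	miR-20b-5p
25-50	miR-153-3p
25-50	miR-200c-5p
25-50	miR-146a-3p
25-50	miR-299b-5p
25-50	miR-129-2-3p
0-25	miR-351-3p
0-25	miR-186-3p
0-25	miR-543-5p
0-25	miR-344b-1-3p
0-25	miR-3084b-3p
0-25	miR-3084d
0-25	miR-3084a-3p
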