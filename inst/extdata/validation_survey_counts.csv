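outcome,mouth,eye,nose
expected,82,62,93
closest_01,24,38,36
closest_02,23,27,21
closest_03,22,19,12
closest_04,17,12,8
closest_05,14,8,14
closest_06,6,5,3
closest_07,6,9,5
closest_08,6,4,6
closest_09,,1,1
closest_10,,5,0
closest_11,,3,1
closest_12,,1,
closest_13,,0,
closest_14,,2,
closest_15,,0,
closest_16,,1,
closest_17,,0,
closest_18,,1,
closest_19,,0,
closest_20,,0,
closest_21,,1,
closest_22,,1,
closest_23,,0,
closest_24,,0,
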