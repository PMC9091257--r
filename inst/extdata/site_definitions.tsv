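site	position
OS5	5.51
OS5	5.54
OS5	5.55
OS5	5.58
OS5	5.61
OS5	5.62
OS5	6.35
OS5	6.38
OS5	6.39
OS5	6.41
OS5	6.42
OS5	6.45
OS5	6.46
OS5	6.49
OS6	6.47
OS6	6.50
OS6	6.53
OS6	6.54
OS6	6.57
OS6	7.33
OS6	7.34
OS6	7.37
OS6	7.38
OS6	7.41
OS9	1.45
OS9	1.49
OS9	1.52
OS9	1.53
OS9	1.56
OS9	7.47
OS9	7.50
OS9	7.51
OS9	7.54
OS9	7.55
OS9	8.48
OS9	8.50
OS9	8.51
OS9	8.54
KS2	3.23
KS2	3.26
KS2	3.27
KS2	3.30
KS2	3.31
KS2	3.34
KS2	4.54
KS2	4.57
KS2	4.58
KS2	4.61
KS2	4.62
KS5	3.41
KS5	3.44
KS5	3.45
KS5	3.48
KS5	3.52
KS5	4.41
KS5	4.44
KS5	4.45
KS5	4.48
KS5	4.52
KS5	4.55
KS5	5.45
KS5	5.46
KS5	5.49
KS5	5.50
KS5	5.53
KS5	5.57
KS8	6.35
KS8	6.36
KS8	6.39
KS8	6.40
KS8	6.42
KS8	6.43
KS8	7.48
KS8	7.51
KS8	7.52
KS8	7.56
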