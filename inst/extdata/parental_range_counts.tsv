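triplet	parent1	parent2	hybrid	within	out	within_pct_printed	out_pct_printed
T121-T126-T121xT126	T121	T126	T121xT126	16371	8828	64.97	35.03
T121-PH4CV-T121xPH4CV	T121	PH4CV	T121xPH4CV	14509	10690	57.58	42.42
T121-PH6WC-T121xPH6WC	T121	PH6WC	T121xPH6WC	14980	10219	59.45	40.55
T126-PH4CV-T126xPH4CV	T126	PH4CV	T126xPH4CV	17027	8172	67.57	32.43
T126-PH6WC-T126xPH6WC	T126	PH6WC	T126xPH6WC	14874	10325	59.03	40.97
PH4CV-PH6WC-PH4CVxPH6WC	PH4CV	PH6WC	PH4CVxPH6WC	15420	9779	61.19	38.81
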