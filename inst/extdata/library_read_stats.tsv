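sample_id	raw_reads	clean_reads	mapped_reads	retention_rate_printed	mapped_rate_printed
T121-1	13871140	13443019	11622834	96.91	86.46
T121-2	16291424	15500533	13091750	95.15	84.46
T126-1	17965773	17397315	14993006	96.84	86.18
T126-2	18368761	17927296	15485598	97.60	86.38
PH4CV-1	14658208	13170436	10408596	89.85	79.03
PH4CV-2	21755428	19974317	16185189	91.81	81.03
PH6WC-1	15884601	15718724	13711443	98.96	87.23
PH6WC-2	14723316	14399270	12569123	97.80	87.29
T121xPH4CV-1	14077347	13499094	11445882	95.89	84.79
T121xPH4CV-2	16779865	16290901	14021578	97.09	86.07
T121xPH6WC-1	18542048	18152498	15750923	97.90	86.77
T121xPH6WC-2	19966028	19316617	16480938	96.75	85.32
T121xT126-1	15417581	15241180	13401570	98.86	87.93
T121xT126-2	16935225	16415063	14049652	96.93	85.59
T126xPH4CV-1	15196264	14513192	12233170	95.51	84.29
T126xPH4CV-2	19608143	18982604	16230126	96.81	85.50
PH4CVxPH6WC-1	14888697	14495750	12502584	97.36	86.25
PH4CVxPH6WC-2	15276520	14917001	12855471	97.65	86.18
T126xPH6WC-1	17312865	16694768	14243976	96.43	85.32
T126xPH6WC-2	15023955	14778806	12903376	98.37	87.31
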