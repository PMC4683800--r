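phase,glycyrrhizic_acid,liquiritin,isoliquiritin,total_flavonoids
1,3.40,3.33,12.22,3.02
2,4.42,7.92,13.20,9.56
3,13.59,12.95,52.35,14.11
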