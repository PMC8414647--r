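sample_id	tissue	health_condition	isotype
REF01	PBMC	Healthy	IGHG
REF02	PBMC	Healthy	IGHG
REF03	PBMC	HIV Infections	IGHG
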