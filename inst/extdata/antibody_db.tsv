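id	source	cdr3_aa	v_call	j_call	c_call	diseases	description
AB001	therapeutic	CARGYGMDVW	IGHV1-8*01	IGHJ4*01		Hypercholesterolemia	synthetic antibody record
AB002	known	CARDLDYW				COVID-19	synthetic antibody record
AB003	known	CARDLDYW				COVID-19; Influenza	synthetic antibody record
AB004	known	CARSSGWYFDYW				COVID-19	synthetic antibody record
AB005	known	CARDGYSSGYW				COVID-19	synthetic antibody record
AB006	known	CTTVYGMDVW				Hypercholesterolemia	synthetic antibody record
AB007	known	CARENTMVRGVW				HIV Infections	synthetic antibody record
AB008	known	CAKDRGYTLDIW				HIV Infections	synthetic antibody record
AB009	known	CARGYSSGWYW				Influenza	synthetic antibody record
AB010	known	CARDAGVAGLFDYW					synthetic antibody record
AB011	known	CVRDREWSELW				HIV Infections	synthetic antibody record
AB012	known	CARWGNYFDSW				COVID-19	synthetic antibody record
AB013	known	CARHNILTGYW				Influenza	synthetic antibody record
AB014	known	CASSLEPSSYEQYW					synthetic antibody record
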