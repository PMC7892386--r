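table	gene	pmid	intervention	effect_on_protein	model	observed_effect	inferred_printed	specificity	species	approach	anomalous
1	EZH2	30327434	Knockout	Removal	Spontaneous	No effect	No effect	Cartilage	Mouse	genetic	FALSE
1	EZH2	31910305	Knockout	Removal	Surgical - MM	Detrimental	Protective	Cartilage inducible	Mouse	genetic	FALSE
1	EZH2	27539752	EPZ005687	Inhibition	Surgical - ACLT	Protective	Detrimental	Articular cavity	Mouse	exogenous	FALSE
1	MINK1	31647983	Knockout	Removal	Spontaneous	Protective	Detrimental	Global	Mouse	genetic	FALSE
1	MINK1	31647983	Knockout	Removal	Surgical - DMM	Detrimental	Protective	Global	Mouse	genetic	FALSE
1	TTR	28941045	Knockout	Removal	Surgical - DMM	Detrimental	Detrimental	Global	Mouse	genetic	TRUE
1	TTR	28941045	Knockout	Removal	Spontaneous	Detrimental	Detrimental	Global	Mouse	genetic	TRUE
1	TTR	28941045	Overexpression	Overexpression	Surgical - DMM	Detrimental	Protective	Global	Mouse	genetic	TRUE
1	CD9	27784871	Knockout	Removal	Surgical - MML + MCL	No effect	No effect	Global	Mouse	genetic	FALSE
1	CD9	27784871	Knockout	Removal	Spontaneous	Protective	Detrimental	Global	Mouse	genetic	FALSE
1	TLR4	31044181	Knockout	Removal	High fat diet	Protective	Detrimental	Global	Mouse	genetic	FALSE
1	TLR4	26245312	Knockout	Removal	Surgical - DMM	No effect	No effect	Global	Mouse	genetic	FALSE
1	TLR4	24703622	Knockout	Removal	Surgical - DMM + MM	No effect	No effect	Global	Mouse	genetic	FALSE
1	RHEB	29991473	Knockout	Removal	Collagenase	Protective	Detrimental	Macrophage	Mouse	genetic	FALSE
1	RHEB	31229684	Overexpression	Overexpression	Surgical - DMM	Protective	Protective	Articular cartilage	Mouse	genetic	FALSE
2	SIRT1	23723318	Knockout	Removal	Surgical - DMM + MM	Detrimental	Protective	Cartilage	Mouse	genetic	FALSE
2	SIRT1	32665267	Knockout	Removal	Surgical - DMM	Detrimental	Protective	Cartilage	Mouse	genetic	FALSE
2	SIRT1	32499111	Knockout	Removal	Surgical - DMM	Detrimental	Protective	Cartilage Inducible	Mouse	genetic	FALSE
2	SIRT1	32499111	Knockout	Removal	Spontaneous	Detrimental	Protective	Cartilage Inducible	Mouse	genetic	FALSE
2	SIRT1	23723318	Knockout	Removal	Spontaneous	Detrimental	Protective	Cartilage	Mouse	genetic	FALSE
2	SIRT1	23587642	Knockout	Removal	Spontaneous	Detrimental	Protective	Global	Mouse	genetic	FALSE
2	SIRT1	23124828	Mutation	Inhibition	Spontaneous	Detrimental	Protective	Global	Mouse	genetic	FALSE
2	SIRT1	22258484	Haploinsufficiency	Deficiency	Spontaneous	Detrimental	Protective	Global	Mouse	genetic	FALSE
2	SIRT1	29922443	SRT1720	Activation	Surgical - DMM	Protective	Protective	Systemic	Mouse	exogenous	FALSE
2	SIRT1	31989845	SRT2104	Activation	Surgical - DMM	Protective	Protective	Articular cavity	Mouse	exogenous	FALSE
2	FYN	29555825	Knockout	Removal	Spontaneous	Protective	Detrimental	Global	Mouse	genetic	FALSE
2	FYN	29555825	Knockout	Removal	Surgical - DMM	Protective	Detrimental	Global	Mouse	genetic	FALSE
2	FYN	31534047	Knockout	Removal	Surgical - DMM	Protective	Detrimental	Global	Mouse	genetic	FALSE
2	FYN	29555825	PP1	Inhibition	Surgical - DMM	Protective	Detrimental	Systemic	Mouse	exogenous	FALSE
2	FYN	29555825	AZD0530	Inhibition	Surgical - DMM	Protective	Detrimental	Systemic	Mouse	exogenous	FALSE
2	TNFRSF11B	30623241	Knockout	Removal	Surgical - TMJ	Detrimental	Protective	Global	Mouse	genetic	FALSE
2	TNFRSF11B	27541035	Knockout	Removal	Spontaneous	Detrimental	Protective	Global	Mouse	genetic	FALSE
2	TNFRSF11B	26018435	Knockout	Removal	Spontaneous	Detrimental	Protective	Global	Mouse	genetic	FALSE
2	TNFRSF11B	17907189	Haploinsufficiency	Deficiency	Spontaneous	Detrimental	Protective	Global	Mouse	genetic	FALSE
2	TNFRSF11B	17907189	Haploinsufficiency	Deficiency	Surgical - DMM	Detrimental	Protective	Global	Mouse	genetic	FALSE
2	TNFRSF11B	17907189	Protein	Increase	Surgical - DMM	Protective	Protective	Articular cavity	Mouse	exogenous	FALSE
2	TNFRSF11B	18668550	Protein	Increase	Surgical - DMM + MM	Protective	Protective	Articular cavity	Mouse	exogenous	FALSE
2	TNFRSF11B	23723320	Protein	Increase	MIA	Protective	Protective	Systemic	Rat	exogenous	FALSE
2	ADAMTS5	21337391	Knockout	Removal	Surgical - DMM	Protective	Detrimental	Global	Mouse	genetic	FALSE
2	ADAMTS5	21337391	Knockout	Removal	Treadmill + TGFB	Protective	Detrimental	Global	Mouse	genetic	FALSE
2	ADAMTS5	19010693	Knockout	Removal	Surgical - DMM	Protective	Detrimental	Global	Mouse	genetic	FALSE
2	ADAMTS5	17968948	Knockout	Removal	Surgical - DMM	Protective	Detrimental	Global	Mouse	genetic	FALSE
2	ADAMTS5	15800624	Knockout	Removal	Surgical - DMM	Protective	Detrimental	Global	Mouse	genetic	FALSE
2	ADAMTS5	23954517	Antibody	Inhibition	STR/ort	Protective	Detrimental	Articular cavity	Mouse	exogenous	FALSE
2	ADAMTS5	26410555	Antibody	Inhibition	Surgical - DMM	Protective	Detrimental	Systemic	Mouse	exogenous	FALSE
2	ADAMTS5	28120109	siRNA	Knockdown	Surgical - DMM	Protective	Detrimental	Articular cavity	Mouse	exogenous	FALSE
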