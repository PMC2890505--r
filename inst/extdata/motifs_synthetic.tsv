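label	kind	pattern	window	min_hydro	region_start	region_end	enabled
Xa	pattern	K-W-x-[ST]-G	NA	NA	NA	NA	TRUE
X	hydrophobic	NA	5	4	1	60	TRUE
I	pattern	G-x-G	NA	NA	NA	NA	TRUE
II	pattern	[DE]-[IL]	NA	NA	NA	NA	TRUE
III	pattern	E-x-[FWY]-G-[KR]	NA	NA	NA	NA	TRUE
IV	pattern	[DNS]-P-P-Y	NA	NA	NA	NA	TRUE
IVa	pattern	R-G-[ST]-x-E	NA	NA	NA	NA	TRUE
V	pattern	D-L-Y-x-x-A-[GS]	NA	NA	NA	NA	TRUE
VI	pattern	G-x(1,6)-[VLIM]	NA	NA	NA	NA	TRUE
VII	hydrophobic	NA	5	4	NA	NA	TRUE
VIII	pattern	NA	NA	NA	NA	NA	FALSE
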