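label	variant	mode
Homo28	11778A	homoplasmic
Homo3	1555G	homoplasmic
Homo34	14484C	homoplasmic
Homo6	3460A	homoplasmic
Homo14	7471.1C	homoplasmic
Homo36	14674C	homoplasmic
Homo7	3635A	homoplasmic
Homo35	14568T	homoplasmic
Homo2	1494T	homoplasmic
Homo19	8993G	homoplasmic
Hetero6	3243R	heteroplasmic
Homo18	8851C	homoplasmic
Homo9	3700A	homoplasmic
Homo21	9176C	homoplasmic
Homo23	9185C	homoplasmic
Homo26	10197A	homoplasmic
Homo31	14459A	homoplasmic
Homo10	3733A	homoplasmic
Homo11	4171A	homoplasmic
Homo16	7511C	homoplasmic
Homo27	10663C	homoplasmic
Homo32	14482A	homoplasmic
Hetero18	3460R	heteroplasmic
Hetero23	4171M	heteroplasmic
Hetero61	11778R	heteroplasmic
Homo1	616C	homoplasmic
Homo13	7445G	homoplasmic
Homo22	9176G	homoplasmic
Homo24	9205- 9206-	homoplasmic
Homo30	13094C	homoplasmic
Hetero20	3733R	heteroplasmic
Hetero25	4300R	heteroplasmic
Hetero31	5650R	heteroplasmic
Hetero33	5703R	heteroplasmic
Hetero43	8344R	heteroplasmic
Hetero55	9185Y	heteroplasmic
Hetero69	13042R	heteroplasmic
Hetero71	13513R	heteroplasmic
Hetero76	14484Y	heteroplasmic
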