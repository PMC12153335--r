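raw	canonical
Finlnad	Finland
Eire	Ireland
French	France
Deutschland	Germany
Holland	Netherlands
USA	United States
U.S.A.	United States
UK	United Kingdom
Great Britain	United Kingdom
PRC	China
Persia	Iran
Burma	Myanmar
Czechia	Czech Republic
East-Africa
West-Africa
Central Asia
Europe
Africa
Asia
Caucasus
Scandinavia
Siberia
unknown
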