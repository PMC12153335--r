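Afghanistan
Argentina
Australia
Austria
Bangladesh
Brazil
Canada
Chile
China
Colombia
Czech Republic
Denmark
Egypt
Estonia
Ethiopia
Finland
France
Germany
Greece
Hungary
Iceland
India
Indonesia
Iran
Iraq
Ireland
Israel
Italy
Japan
Kenya
Mexico
Mongolia
Morocco
Myanmar
Nepal
Netherlands
New Zealand
Nigeria
Norway
Pakistan
Papua New Guinea
Peru
Philippines
Poland
Portugal
Russia
Saudi Arabia
Somalia
South Africa
South Korea
Spain
Sudan
Sweden
Switzerland
Tanzania
Thailand
Turkey
Uganda
Ukraine
United Kingdom
United States
Vietnam
Yemen
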