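country	synonyms
USA	United States|United States of America|U.S.A.|U.S.|US
United Kingdom	UK|U.K.|Great Britain|Britain|England|Scotland|Wales|Northern Ireland
France	French Republic
Germany	Deutschland|Federal Republic of Germany
Spain	Espana|España
Portugal	
Italy	Italia
Netherlands	The Netherlands|Holland
Belgium	
Switzerland	
Austria	
Norway	
Sweden	
Finland	
Denmark	
Iceland	
Ireland	Republic of Ireland
Poland	
Czech Republic	Czechia
Slovakia	
Hungary	
Romania	
Bulgaria	
Greece	
Turkey	Turkiye|Türkiye
Russia	Russian Federation|USSR
Ukraine	
Estonia	
Latvia	
Lithuania	
Canada	
Mexico	
Guatemala	
Costa Rica	
Panama	
Cuba	
Brazil	Brasil
Argentina	
Chile	
Peru	
Colombia	
Ecuador	
Bolivia	
Venezuela	
Uruguay	
Paraguay	
China	People's Republic of China|PRC
Japan	
South Korea	Republic of Korea|Korea
Taiwan	
India	
Pakistan	
Bangladesh	
Sri Lanka	
Nepal	
Thailand	
Viet Nam	Vietnam
Cambodia	
Laos	Lao PDR
Myanmar	Burma
Malaysia	
Singapore	
Indonesia	
Philippines	
Mongolia	
Kazakhstan	
Iran	Islamic Republic of Iran
Iraq	
Israel	
Saudi Arabia	
United Arab Emirates	UAE
Egypt	
Morocco	
Algeria	
Tunisia	
Libya	
Ethiopia	
Kenya	
Tanzania	United Republic of Tanzania
Uganda	
Nigeria	
Ghana	
Cameroon	
Democratic Republic of the Congo	DR Congo|DRC|Congo-Kinshasa
South Africa	
Namibia	
Botswana	
Zimbabwe	
Mozambique	
Madagascar	
Australia	
New Zealand	Aotearoa
Papua New Guinea	PNG
Fiji	
New Caledonia	
French Polynesia	
Solomon Islands	
Vanuatu	
Greenland	
Antarctica	
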