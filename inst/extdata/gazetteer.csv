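surface_form,country
italy,IT
italian,IT
italians,IT
rome,IT
milan,IT
bergamo,IT
brescia,IT
turin,IT
naples,IT
venice,IT
bologna,IT
florence,IT
lombardy,IT
veneto,IT
united kingdom,GB
uk,GB
britain,GB
british,GB
england,GB
scotland,GB
wales,GB
london,GB
manchester,GB
birmingham,GB
liverpool,GB
glasgow,GB
edinburgh,GB
leeds,GB
bristol,GB
united states,US
usa,US
america,US
american,US
americans,US
new york,US
los angeles,US
chicago,US
seattle,US
boston,US
houston,US
philadelphia,US
san francisco,US
santa clara,US
washington,US
california,US
texas,US
florida,US
canada,CA
canadian,CA
canadians,CA
toronto,CA
vancouver,CA
montreal,CA
ottawa,CA
calgary,CA
edmonton,CA
winnipeg,CA
quebec,CA
ontario,CA
alberta,CA
china,CN
chinese,CN
wuhan,CN
beijing,CN
shanghai,CN
hubei,CN
guangzhou,CN
shenzhen,CN
chongqing,CN
tianjin,CN
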