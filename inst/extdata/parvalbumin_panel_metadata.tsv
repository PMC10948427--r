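allergen_id	species	complete	includes_initial_met
Clu h 1.0101	Clupea harengus	TRUE	TRUE
Clu h 1.0201	Clupea harengus	TRUE	TRUE
Clu h 1.0301	Clupea harengus	TRUE	TRUE
Cyp c 1.0101	Cyprinus carpio	TRUE	TRUE
Cyp c 1.0201	Cyprinus carpio	TRUE	TRUE
Gad c 1.0101	Gadus callarias	TRUE	FALSE
Gad m 1.0101	Gadus morhua	TRUE	TRUE
Gad m 1.0102	Gadus morhua	TRUE	TRUE
Gad m 1.0201	Gadus morhua	TRUE	TRUE
Gad m 1.0202	Gadus morhua	TRUE	TRUE
Lat c 1.0101	Lates calcarifer	TRUE	TRUE
Lat c 1.0201	Lates calcarifer	TRUE	TRUE
Lep w 1.0101	Lepidorhombus whiffiagonis	TRUE	TRUE
Onc m 1.0101	Oncorhynchus mykiss	FALSE	FALSE
Onc m 1.0201	Oncorhynchus mykiss	FALSE	FALSE
Sal s 1.0101	Salmo salar	TRUE	TRUE
Sar sa 1.0101	Sardinops sagax	TRUE	TRUE
Seb m 1.0101	Sebastes marinus	TRUE	TRUE
Seb m 1.0201	Sebastes marinus	TRUE	TRUE
Thu a 1.0101	Thunnus albacares	TRUE	TRUE
Xip g 1.0101	Xiphias gladius	TRUE	TRUE
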