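((Columba_livia:92,(Amazona_amazonica:60,((Aphelocoma_californica:18,Garrulus_glandarius:18):21,((Melospiza_melodia:5,Melospiza_georgiana:5):20,Taeniopygia_guttata:25):14):21):32):220,((Canis_latrans:2,(Canis_lupus:0.015,Canis_familiaris:0.015):1.985):92,((Sciurus_niger:70,Meriones_unguiculatus:70):19,((Daubentonia_madagascariensis:59,(Propithecus_coquereli:38,(Varecia_variegata:30,(Lemur_catta:22,(Eulemur_rubriventer:10,(Eulemur_mongoz:8,(Eulemur_fulvus:6,Eulemur_macaco:6):2):2):12):8):8):21):15,(((Cebus_apella:21,Saimiri_sciureus:21):2,(Callithrix_jacchus:12,Leontopithecus_chrysomelas:12):11):20,((Rhinopithecus_roxellana:18,(Macaca_mulatta:13,(Papio_anubis:1.8,Papio_hamadryas:1.8):11.2):5):13,(Pongo_pygmaeus:17,(Gorilla_gorilla:9,(Pan_paniscus:2.5,Pan_troglodytes:2.5):6.5):8):14):12):31):15):5):218);
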