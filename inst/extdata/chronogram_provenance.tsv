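node	age_myr	source
Aves-Mammalia root	312	TimeTree median, amniote crown
Columbiformes vs core landbirds	92	TimeTree median, Neoaves
Psittaciformes vs Passeriformes	60	TimeTree median, Psittacopasserae
Corvidae vs Passerida	39	TimeTree median
Aphelocoma californica vs Garrulus glandarius	18	TimeTree median, Corvidae crown
Passeroidea (Melospiza lineage vs Taeniopygia)	25	TimeTree median
Melospiza melodia vs Melospiza georgiana	5	TimeTree median
Laurasiatheria vs Euarchontoglires	94	TimeTree median, Boreoeutheria
Canis latrans vs Canis lupus lineage	2	TimeTree median, crown Canis
Canis lupus vs Canis familiaris	0.015	15 kya domestication-era split (Skoglund et al.)
Glires vs Primates	89	TimeTree median, Euarchontoglires crown
Sciurus niger vs Meriones unguiculatus	70	TimeTree median, Rodentia crown
Strepsirrhini vs Haplorhini	74	TimeTree/10kTrees, Primates crown
Daubentonia vs Lemuroidea	59	TimeTree/10kTrees
Propithecus vs Lemuridae	38	TimeTree/10kTrees
Varecia vs (Lemur, Eulemur)	30	10kTrees
Lemur catta vs Eulemur	22	10kTrees
Eulemur crown (rubriventer first)	10	10kTrees
Eulemur mongoz vs (fulvus, macaco)	8	10kTrees
Eulemur fulvus vs Eulemur macaco	6	10kTrees
Platyrrhini vs Catarrhini	43	TimeTree/10kTrees, Simiiformes crown
Cebidae vs Callitrichidae	23	10kTrees
Cebus apella vs Saimiri sciureus	21	10kTrees
Callithrix jacchus vs Leontopithecus chrysomelas	12	10kTrees
Cercopithecidae vs Hominidae	31	TimeTree/10kTrees, Catarrhini crown
Colobinae (Rhinopithecus) vs Cercopithecinae	18	10kTrees
Macaca vs Papio	13	10kTrees
Papio anubis vs Papio hamadryas	1.8	10kTrees
Pongo vs African apes	17	TimeTree/10kTrees
Gorilla vs Pan	9	TimeTree/10kTrees
Pan paniscus vs Pan troglodytes	2.5	TimeTree/10kTrees
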