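library	clone_id	nearest_neighbor	division	identity
KD	KD1	Vibrio vulnificus	gamma-Proteobacteria	60
KD	KD2	Meiothermus ruber	Deinococcus	59
KD	KD3	Arcticibacter svalbardensis	Bacteroidetes	83
KD	KD4	Olivibacter sitiensis	Bacteroidetes	69
KD	KD5	Segetibacter koreensis	Bacteroidetes	69
KD	KD6	Flavobacterium sp.	Bacteroidetes	76
KD	KD7	Exiguobacterium sp.	Firmicutes	99
KD	KD8	Tumebacillus flagellatus	Firmicutes	98
KD	KD9	Alteromonas macleodii	gamma-Proteobacteria	98
KD	KD10	Ensifer adhaerens	alpha-Proteobacteria	96
KD	KD11	Azospirillum brasilense	alpha-Proteobacteria	99
KD	KD12	Rhodopseudomonas palustris	alpha-Proteobacteria	97
KD	KD13	Rhodovulum sp.	alpha-Proteobacteria	98
KD	KD14	Burkholderia mimosarum	beta-Proteobacteria	98
KD	KD15	Halobacillus sp	Firmicutes	97
KD	KD16	Thermobacillus composti	Firmicutes	98
KD	KD17	Thermoanaerobacterium xylanolyticum	Firmicutes	98
KD	KD18	Paenibacillus sp.	Firmicutes	98
KD	KD19	Devosia limi	alpha-Proteobacteria	87
KD	KD20	Sphingobacterium sp.	Bacteroidetes	99
CD	CD1	Formosa agariphila	Bacteroidetes	89
CD	CD2	Arenibacter algicola	Bacteroidetes	73
CD	CD3	Streptosporangium roseum	Actinobacteria	71
CD	CD4	Paenibacillus	Firmicutes	98
CD	CD5	Pontibacter korlensis	Bacteroidetes	98
CD	CD6	Spirosoma radiotolerans	Bacteroidetes	98
CD	CD7	Hymenobacter swuensis	Bacteroidetes	97
CD	CD8	Streptomyces sp.	Actinobacteria	95
CD	CD9	Flavobacterium sp.	Bacteroidetes	74
CD	CD10	Flavobacterium subsaxonicum	Bacteroidetes	74
CD	CD11	Flavobacterium sp.	Bacteroidetes	77
CD	CD12	Flavobacterium hibernum	Bacteroidetes	74
CD	CD13	Sphingobacterium sp.	Bacteroidetes	84
CD	CD14	Cytophaga hutchinsonii	Bacteroidetes	60
CD	CD15	Pedobacter sp.	Bacteroidetes	84
CD	CD16	Pedobacter heparinus	Bacteroidetes	83
CD	CD17	Cellulophaga baltica	Bacteroidetes	99
CD	CD18	[Clostridium] termitidis	Firmicutes	98
CD	CD19	Clostridium straminisolvens	Firmicutes	97
CD	CD20	Clostridium cellulovorans	Firmicutes	97
CM	CM1	Arenibacter algicola	Bacteroidetes	73
CM	CM2	Verrucomicrobiae bacterium	Chlamydiae	64
CM	CM3	Zunongwangia profunda	Bacteroidetes	63
CM	CM4	Pontibacter korlensis	Bacteroidetes	66
CM	CM5	Cellulophaga baltica	Bacteroidetes	74
CM	CM6	Mucilaginibacter paludis	Bacteroidetes	70
CM	CM7	Maribacter sp.	Bacteroidetes	72
CM	CM8	Spirosoma lingual	Bacteroidetes	68
CM	CM9	Adhaeribacter aquaticus	Bacteroidetes	69
CM	CM10	Elizabethkingia miricola	Bacteroidetes	73
CM	CM11	Vibrio vulnificus	gamma-Proteobacteria	99
CM	CM12	Gynuella sunshinyii	gamma-Proteobacteria	100
CM	CM13	Vibrio campbellii	gamma-Proteobacteria	59
CM	CM14	Devosia	alpha-Proteobacteria	89
CM	CM15	Sinorhizobium fredii	alpha-Proteobacteria	99
CM	CM16	Paenibacillus	Firmicutes	99
CM	CM17	Bacillus akibai	Firmicutes	98
CM	CM18	Actinospica acidiphila	Actinobacteria	97
CM	CM19	Streptomyces sp.	Actinobacteria	96
CM	CM20	Clostridium cellulovorans	Firmicutes	98
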