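database	raw	target
kegg	gene	protein
kegg	compound	abundance
kegg	map	bioprocess
kegg	group	complex
kegg	ortholog	protein
kegg	enzyme	protein
wikipathways	GeneProduct	protein
wikipathways	Protein	protein
wikipathways	Rna	rna
wikipathways	Metabolite	abundance
wikipathways	Pathway	bioprocess
wikipathways	Complex	complex
wikipathways	Group	complex
wikipathways	DataNode	abundance
reactome	Protein	protein
reactome	Rna	rna
reactome	Dna	gene
reactome	SmallMolecule	abundance
reactome	PhysicalEntity	abundance
reactome	Complex	complex
reactome	EntitySet	family
reactome	Pathway	bioprocess
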