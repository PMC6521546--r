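database	raw	target
kegg	activation	increases
kegg	expression	increases
kegg	inhibition	decreases
kegg	repression	decreases
kegg	phosphorylation	directly_increases
kegg	dephosphorylation	directly_decreases
kegg	ubiquitination	directly_increases
kegg	glycosylation	directly_increases
kegg	methylation	directly_increases
kegg	binding/association	association
kegg	indirect effect	regulates
kegg	compound_mediated	association
kegg	hidden compound	SKIP
kegg	state change	SKIP
kegg	dissociation	SKIP
kegg	missing interaction	SKIP
wikipathways	Arrow	increases
wikipathways	mim-stimulation	increases
wikipathways	mim-conversion	increases
wikipathways	TBar	decreases
wikipathways	mim-inhibition	decreases
wikipathways	mim-catalysis	increases
wikipathways	mim-binding	association
wikipathways	Line	association
reactome	ACTIVATION	increases
reactome	INHIBITION	decreases
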