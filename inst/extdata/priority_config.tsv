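# namespace priority lists per modality (comma-separated, highest first)
genes	hgnc,uniprot,ncbigene,ensembl,<native>
metabolites	chebi,pubchem.compound,<native>
mirnas	mirbase,hgnc,<native>
bioprocess	<native>
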