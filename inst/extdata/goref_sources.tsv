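# Default mapping of GAF DB:Reference ids to electronic-annotation
# source labels (the six UniProt-GOA inference pipelines).
GO_REF:0000002	interpro
GO_REF:0000003	ec2go
GO_REF:0000004	uniprotkb_kw
GO_REF:0000019	ensembl_compara
GO_REF:0000020	hamap2go
GO_REF:0000023	uniprot_subcell
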