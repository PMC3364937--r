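!gaf-version: 2.0
UniProtKB	P00001	g1		GO:0000003	GO_REF:0000002	IEA		P			protein	taxon:9606	20080101	UniProt		
UniProtKB	P00001	g1		GO:0000003	PMID:1000001	IDA		P			protein	taxon:9606	20110101	SGD		
UniProtKB	P00002	g2	NOT	GO:0000002	PMID:1000002	IDA		P			protein	taxon:9606	20110101	SGD		
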