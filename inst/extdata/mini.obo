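format-version: 1.2
ontology: mini-go

[Term]
id: GO:0000001
name: biological process root
namespace: biological_process

[Term]
id: GO:0000002
name: organelle organization
namespace: biological_process
is_a: GO:0000001 ! biological process root

[Term]
id: GO:0000003
name: mitochondrion organization
namespace: biological_process
alt_id: GO:0000099
is_a: GO:0000002 ! organelle organization

[Term]
id: GO:0000004
name: mitochondrial fission
namespace: biological_process
is_a: GO:0000003 ! mitochondrion organization

[Term]
id: GO:0000005
name: vacuole organization
namespace: biological_process
is_a: GO:0000002 ! organelle organization

[Term]
id: GO:0000010
name: molecular function root
namespace: molecular_function

[Term]
id: GO:0000011
name: catalytic activity
namespace: molecular_function
is_a: GO:0000010 ! molecular function root

[Term]
id: GO:0000020
name: cellular component root
namespace: cellular_component

[Term]
id: GO:0000021
name: organelle
namespace: cellular_component
is_a: GO:0000020 ! cellular component root

[Term]
id: GO:0000022
name: mitochondrion
namespace: cellular_component
is_a: GO:0000021 ! organelle

[Term]
id: GO:0000098
name: obsolete nucleolar chromatin
namespace: cellular_component
is_obsolete: true
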