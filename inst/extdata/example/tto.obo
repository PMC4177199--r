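format-version: 1.2
ontology: tto-example

[Term]
id: TTO:0000001
name: Actinopterygii
property_value: has_rank RANK:0000009
xref: TTO:0000001

[Term]
id: TTO:0000002
name: Cypriniformes
is_a: TTO:0000001 ! Actinopterygii
property_value: has_rank RANK:0000015
xref: TTO:0000002

[Term]
id: TTO:0000003
name: Cyprinidae
is_a: TTO:0000002 ! Cypriniformes
property_value: has_rank RANK:0000020
xref: TTO:0000003

[Term]
id: TTO:0000004
name: Danio
is_a: TTO:0000003 ! Cyprinidae
property_value: has_rank RANK:0000024
xref: TTO:0000004

[Term]
id: TTO:0000005
name: Danio rerio
is_a: TTO:0000004 ! Danio
synonym: "Brachydanio rerio" RELATED TAXONOMIC []
property_value: has_rank RANK:0000028
xref: TTO:0000005

[Term]
id: TTO:0000006
name: Danio rerio frankei
is_a: TTO:0000005 ! Danio rerio
property_value: has_rank RANK:0000029
xref: TTO:0000006

[Term]
id: TTO:0000007
name: Danio kyathit
is_a: TTO:0000004 ! Danio
synonym: "Danio kyathith" EXACT MISSPELLING []
property_value: has_rank RANK:0000028
xref: TTO:0000007
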