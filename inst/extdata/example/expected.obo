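format-version: 1.2
ontology: example-vertebrate-taxonomy

[Term]
id: TXO:0000001
name: Actinopterygii
is_a: TXO:0000026 ! Vertebrata
xref: NCBI:2
xref: TTO:0000001
property_value: has_rank RANK:0000009

[Term]
id: TXO:0000002
name: Ambystoma
is_a: TXO:0000004 ! Ambystomatidae
xref: AWEB:0000009
property_value: has_rank RANK:0000024

[Term]
id: TXO:0000003
name: Ambystoma mexicanum
is_a: TXO:0000002 ! Ambystoma
synonym: "Axolotl" EXACT COMMONNAME []
xref: AWEB:0000010
property_value: has_rank RANK:0000028

[Term]
id: TXO:0000004
name: Ambystomatidae
is_a: TXO:0000009 ! Caudata
xref: AWEB:0000008
property_value: has_rank RANK:0000020

[Term]
id: TXO:0000005
name: Amphibia
is_a: TXO:0000026 ! Vertebrata
xref: AWEB:0000001
xref: NCBI:3
property_value: has_rank RANK:0000009

[Term]
id: TXO:0000006
name: Anura
is_a: TXO:0000005 ! Amphibia
xref: AWEB:0000002
xref: NCBI:7
property_value: has_rank RANK:0000015

[Term]
id: TXO:0000007
name: Brontotheriidae
is_a: TXO:0000015 ! Mammalia
xref: PBDB:0000003
property_value: has_rank RANK:0000020
property_value: is_extinct "true" xsd:boolean

[Term]
id: TXO:0000008
name: Brontotherium
is_a: TXO:0000007 ! Brontotheriidae
synonym: "Titanops" RELATED TAXONOMIC []
xref: PBDB:0000004
property_value: has_rank RANK:0000024
property_value: is_extinct "true" xsd:boolean

[Term]
id: TXO:0000009
name: Caudata
is_a: TXO:0000005 ! Amphibia
xref: AWEB:0000007
property_value: has_rank RANK:0000015

[Term]
id: TXO:0000010
name: Cyprinidae
is_a: TXO:0000011 ! Cypriniformes
xref: TTO:0000003
property_value: has_rank RANK:0000020

[Term]
id: TXO:0000011
name: Cypriniformes
is_a: TXO:0000001 ! Actinopterygii
xref: NCBI:5
xref: TTO:0000002
property_value: has_rank RANK:0000015

[Term]
id: TXO:0000012
name: Danio
is_a: TXO:0000010 ! Cyprinidae
xref: TTO:0000004
property_value: has_rank RANK:0000024

[Term]
id: TXO:0000013
name: Danio kyathit
is_a: TXO:0000012 ! Danio
synonym: "Danio kyathith" EXACT MISSPELLING []
xref: TTO:0000007
property_value: has_rank RANK:0000028

[Term]
id: TXO:0000014
name: Danio rerio
is_a: TXO:0000012 ! Danio
synonym: "Brachydanio rerio" RELATED TAXONOMIC []
synonym: "Danio rerio frankei" NARROW SUBSPECIES []
synonym: "zebrafish" EXACT COMMONNAME []
xref: NCBI:6
xref: TTO:0000005
xref: TTO:0000006
property_value: has_rank RANK:0000028

[Term]
id: TXO:0000015
name: Mammalia
is_a: TXO:0000026 ! Vertebrata
xref: NCBI:4
property_value: has_rank RANK:0000009
comment: Allotherian orders retained pending revision of published treatments.

[Term]
id: TXO:0000016
name: Multituberculata
xref: PBDB:0000001
property_value: has_rank RANK:0000015
property_value: is_extinct "true" xsd:boolean
is_obsolete: true

[Term]
id: TXO:0000017
name: Mus
is_a: TXO:0000025 ! Rodentia
xref: NCBI:11
property_value: has_rank RANK:0000024

[Term]
id: TXO:0000018
name: Mus musculus
is_a: TXO:0000017 ! Mus
synonym: "house mouse" EXACT COMMONNAME []
xref: NCBI:12
property_value: has_rank RANK:0000028

[Term]
id: TXO:0000019
name: Primates
is_a: TXO:0000015 ! Mammalia
xref: NCBI:10
property_value: has_rank RANK:0000015

[Term]
id: TXO:0000020
name: Ptilodus
is_a: TXO:0000026 ! Vertebrata
xref: PBDB:0000002
property_value: has_rank RANK:0000024
property_value: is_extinct "true" xsd:boolean

[Term]
id: TXO:0000021
name: Rana
is_a: TXO:0000024 ! Ranidae
xref: AWEB:0000004
property_value: has_rank RANK:0000024

[Term]
id: TXO:0000022
name: Rana catesbeiana
is_a: TXO:0000021 ! Rana
synonym: "American Bullfrog" EXACT COMMONNAME []
synonym: "Lithobates catesbeianus" RELATED TAXONOMIC []
xref: AWEB:0000005
xref: NCBI:8
property_value: has_rank RANK:0000028

[Term]
id: TXO:0000023
name: Rana temporaria
is_a: TXO:0000021 ! Rana
synonym: "European Common Frog" EXACT COMMONNAME []
xref: AWEB:0000006
property_value: has_rank RANK:0000028

[Term]
id: TXO:0000024
name: Ranidae
is_a: TXO:0000006 ! Anura
xref: AWEB:0000003
property_value: has_rank RANK:0000020

[Term]
id: TXO:0000025
name: Rodentia
is_a: TXO:0000015 ! Mammalia
xref: NCBI:9
property_value: has_rank RANK:0000015

[Term]
id: TXO:0000026
name: Vertebrata
xref: NCBI:1

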