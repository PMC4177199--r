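1	|	Vertebrata	|		|	scientific name	|
2	|	Actinopterygii	|		|	scientific name	|
3	|	Amphibia	|		|	scientific name	|
4	|	Mammalia	|		|	scientific name	|
5	|	Cypriniformes	|		|	scientific name	|
6	|	Danio rerio	|		|	scientific name	|
6	|	zebrafish	|		|	genbank common name	|
7	|	Anura	|		|	scientific name	|
8	|	Rana catesbeiana	|		|	scientific name	|
9	|	Rodentia	|		|	scientific name	|
10	|	Primates	|		|	scientific name	|
11	|	Mus	|		|	scientific name	|
12	|	Mus musculus	|		|	scientific name	|
12	|	house mouse	|		|	genbank common name	|
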