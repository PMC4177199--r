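1	|	1	|		|
2	|	1	|	class	|
3	|	1	|	class	|
4	|	1	|	class	|
5	|	2	|	order	|
6	|	5	|	species	|
7	|	3	|	order	|
8	|	7	|	species	|
9	|	4	|	order	|
10	|	4	|	order	|
11	|	9	|	genus	|
12	|	11	|	species	|
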