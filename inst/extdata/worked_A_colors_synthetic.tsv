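adjacency	color
5t-$	a
1h-5h	a
1t-2h	b
2t-6t	b
4h-6h	c
4t-8h	c
8t-$	d
3h-$	d
3t-7t	a
7h-$	b
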