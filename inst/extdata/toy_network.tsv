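% four-node directed weighted worked example
% directed=TRUE weighted=TRUE
a	b	1
a	d	4
b	c	2
c	a	3
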