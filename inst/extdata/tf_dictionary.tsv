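HIF-1	HIF-1|HIF1|hypoxia-inducible factor-1|hypoxia-inducible factor 1
CREB	CREB|cAMP response element-binding protein
E2F1	E2F1
AP1	AP1|activator protein 1
VHL	VHL|von Hippel-Lindau protein
p300	p300|EP300
TFIIB	TFIIB
TBP	TBP|TATA-binding protein
CBP	CBP|CREB-binding protein
p53	p53|TP53
ELK1	ELK1
SP1	SP1
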