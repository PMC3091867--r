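EPO	EPO|erythropoietin
VEGF	VEGF|vascular endothelial growth factor
LDHA	LDHA|lactate dehydrogenase A
ALDOA	ALDOA|aldolase-A|aldolase A
PGK1	PGK1|phosphoglycerate kinase
ENO1	ENO1|enolase-1|enolase 1
ABCA4	ABCA4|ATP-binding cassette sub-family A (ABC1), member 4
CBP	CBP
p53	p53
GLUT1	GLUT1|glucose transporter 1
MCP-1	MCP-1
TERT	TERT
CAIX	CAIX|carbonic anhydrase IX
NOS2	NOS2
BNIP3	BNIP3
HMOX1	HMOX1|heme oxygenase 1
CXCL12	CXCL12
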