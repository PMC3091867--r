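9748288	Hypoxia-inducible factor-1 mediates transcriptional activation of LDHA in hypoxic cells.	Recent reports described a role for the hyposia-inducible factor-1 (HIF-1) in the transcriptional activation of lactate dehydrogenase A, aldolase-A, phosphoglycerate kinase, and enolase-1 genes.
11375890	HIF-1 regulates p53 under hypoxia.	Hypoxia-inducible factor-1 (HIF-1) directly regulates the p53 gene. Induction of p53 by HIF-1 was observed in hypoxic tissue.
90000001	HIF-1 activates VHL in renal carcinoma.	HIF-1 strongly activates VHL in renal tissue. VHL binds p53 in these samples. The von Hippel-Lindau protein (VHL) represses GLUT1.
90000002	Erythropoietin induction by hypoxia-inducible factor 1.	Induction of EPO by HIF-1 was observed. HIF-1 activation of EPO and VEGF occurs under low oxygen.
90000003	Tissue profiles of cultured samples.	EPO and VEGF were measured in cultured samples. No regulation statement appears here.
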