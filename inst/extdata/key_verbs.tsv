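activate	activate|activates|activated|activating|activation
induce	induce|induces|induced|inducing|induction
regulate	regulate|regulates|regulated|regulating|regulation
repress	repress|represses|repressed|repression
bind	bind|binds|bound|binding
inhibit	inhibit|inhibits|inhibited|inhibition
suppress	suppress|suppresses|suppressed|suppression
express	express|expresses|expressed|expression
respond	respond|responds|responded|response
transactivate	transactivate|transactivates|transactivated|transactivation
stimulate	stimulate|stimulates|stimulated|stimulation
mediate	mediate|mediates|mediated|mediation
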