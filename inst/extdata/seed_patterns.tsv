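# Illustrative seed patterns (one canonical pattern per line); real
# analyses supply their own curated seed file.
[TF/TG].*activates.*[TF/TG]
[TF/TG].*activation.*of.*[TF/TG]
[TF/TG].*induces.*[TF/TG]
[TF/TG].*induced.*by.*[TF/TG]
induction.*of.*[TF/TG].*by.*[TF/TG]
[TF/TG].*regulates.*[TF/TG]
[TF/TG].*regulation.*of.*[TF/TG]
[TF/TG].*binding.*[TF/TG]
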