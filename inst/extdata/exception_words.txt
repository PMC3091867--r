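# Dictionary names that collide with common English words; never tagged.
To
Alpha
Cell
An
Set
Was
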