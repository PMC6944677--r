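# affected member ids (demo)
III-1
II-2
II-4
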