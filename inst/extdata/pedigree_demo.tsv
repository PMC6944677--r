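# SYNTHETIC demo pedigree (the published pedigree figure is not
# machine-readable): three generations, maternal links only.
# Matriline of I-2: I-2, II-2, II-4, II-6, III-1, III-2, III-3 (7 members).
child	mother
II-2	I-2
II-4	I-2
II-6	I-2
III-1	II-2
III-2	II-2
III-3	II-4
III-4	II-5
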