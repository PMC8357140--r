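error_class	n_files
d-mmm	1797
slash-date	19
scientific	4
five-digit-serial	340
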