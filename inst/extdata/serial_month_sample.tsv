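months	n_files
march_or_september	292
other	48
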