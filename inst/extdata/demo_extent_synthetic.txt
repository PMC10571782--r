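33.4164546718 101.8690823184 33.4145992003 101.8716401104
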