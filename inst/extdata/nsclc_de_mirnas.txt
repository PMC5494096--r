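miR-145-5p
miR-204-5p
miR-182-5p
miR-567
miR-141-3p
miR-454-3p
miR-590-3p
miR-338-3p
miR-139-5p
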