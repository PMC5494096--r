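# Literature-reported NSCLC adenocarcinoma miRNA biomarkers (reported ids;
# entries without a -3p/-5p arm suffix match any arm)
miR-155
miR-196a-5p
miR-218-5p
miR-143
miR-182
miR-650
miR-141
miR-29c
miR-23b-3p
miR-10b-5p
miR-21-5p
miR-126-3p
miR-451a
miR-25
miR-145
miR-210
miR-142-3p
miR-29b
miR-590
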