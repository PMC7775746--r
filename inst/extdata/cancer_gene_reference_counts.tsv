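label	catalog_size	target_count
ONG	808	533
TSG	1247	843
OncoTSG	244	170
AllTargets	NA	15796
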