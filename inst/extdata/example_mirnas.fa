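>hsa-let-7a-5p
UGAGGUAGUAGGUUGUAUAGUU
>syn-miR-1 synthetic example miRNA (not a biological sequence)
UCACAGUGGCUAAGUUCUGC
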