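helix,first_resid,last_resid,note
TM1,8,34,reconstructed from cytoplasmic-open LacY topology annotations; approximate
TM4,105,129,reconstructed from cytoplasmic-open LacY topology annotations; approximate
TM7,221,248,reconstructed from cytoplasmic-open LacY topology annotations; approximate
TM10,310,334,reconstructed from cytoplasmic-open LacY topology annotations; approximate
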