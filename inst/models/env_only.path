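# Environment-only path model (reconstructed): temperature as the
# environmental-gradient representative, SIN and soil covariates driving
# the nitrogen-function composite directly.
MAT -> SIN
MAT -> TOC
MAT -> MC
MAT -> Fe
SIN -> Nfunc
TOC -> Nfunc
MC -> Nfunc
Fe -> Nfunc
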