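# Phylogeny-mediated path model (reconstructed): adds a phylogenetic
# diversity composite (first PC of NRI/NTI/MPD/MNTD) mediating the
# SIN -> nitrogen-function relationship.
MAT -> SIN
MAT -> TOC
MAT -> MC
MAT -> Fe
SIN -> PhyloDiv
PhyloDiv -> Nfunc
SIN -> Nfunc
TOC -> Nfunc
MC -> Nfunc
Fe -> Nfunc
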