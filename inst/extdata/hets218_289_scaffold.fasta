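>HET-s_218-289 scaffold prion domain, Podospora anserina (UniProt Q03689 residues 218-289); first residue = author number 218
KIDAIVGRNSAKDIRTEERARVQLGNVVTAAALHGGIRISDQTTNSVETVVGKGESRVLI
GNEYGGKGFWDN
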