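# md5 checksums of the benzene wavefunction fixtures
b4c95b840e26654f7602839aab9d03f6  benzene_rhf_631gd.molden
96a046f381db521e1cd1e572a6a7135a  benzene_cas66.civec
602df39690dd75a565631e8b0ac04736  benzene_cas3018.civec
f1c9c3df8c673cbe1a96102903770bc4  benzene_reference_values.tsv
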