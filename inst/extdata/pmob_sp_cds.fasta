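>PmoB_sp U31650.2 Methylosinus trichosporium OB3b pmoB signal peptide CDS
atgaaagctctggaaagaatggccgaactggcgaccggacgggtcggaaagctcctcggc
ctgagcgttgcggctgcggtcgccgcgacggcggcttcggtggccccggcggaagcg
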