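>g1_s1
CAATGAATACCGAGCACTCCCTCCTAAGGAGATTTTTTGCTTGGATCTTGTAATTGACAAACCAGAACTACATGACCACTAGCGAATGCAAAGATGTACTTCATATTCGCGCGTACATACCTGGGTGTGATGGGATTGCCAGCGAAGCTCGCCAGCCGGACCACGAACATACAGTATTCTGACACCACAGAACAATGTTCAAGGAGCTTATGTATATCTGGTGAAACCATCTGTAACACTCTCGGATAATCGGTATAGATCAAGAAAAGTCTTAGCGGGACCCGTCATATTTCCGGACTCTAGGCTCAGCTGG
>g1_s2
CAATGAATACCGAGCACTCCCTCCTAAGGAGATTTTTTGCTTGGATCTTGTAATTGACAAACCAGAACTACATGACCAATAGCGAATGCAAAGATGTACTTCATATTCGCGCGTACATACCTGGATGTGATGGGATTGCCAGCGAAGCTCGCCAGCCGGACCACGAACATACAGTATTCTGACACCACAGAACAATGTTCAAGGAGCTTATGTATATGTGGTGAAACCATCTGTAACACTCTCGGATAATCGGTATAGATCAAGAAAAGTCTTAGCGGGACCCGTCATATTTCCGGACTCTAGGCTCAGCTGG
>g1_s3
CAATGAATACCGAGCACTCCCTCCTAAGGAGATTTTTTGCTTGGATCTTGTAATTGACAAACCAGAACTACATGGCCACTAGCGAATGCAAAGATGTACATCATATTCGCGCGTACATACCTGGATGTGATGGGATTGCCAGCGAAGCTCGCCAGCCGGATCACGAACATACAGTATTCTGACACCACAGAACAATGTTCAAGGAGCTTATGTATATCTGGTGAAACCATCTGTAACACTCTCGGATAATCGGTATAGATCAAGAAAAGTCTTAGCGGGACCCGTCATCTTTCCGGACTCTAGGCTCAGCTGG
>g1_s4
CAATGAATACCGAGCACTCCCTCCTAAGGAGATTTTTTGCTTGGATCTTGTAATTGACAAACCAGAACTACATGACCACTAGCGAATGCAAAGATGTACTTCATATTCGCGCGTACATACCTGGATGTGATGGGATTGCCAGCGAAGCTCGCCAGCCGGACCACGAACATACAGTATTCTGACACCACAGAACAATGTTCAAGGAGCTTATGTATATCTGGTGAAACCATCTGTAACACTCTCGGATAATCGGTATAGATCAAGAAAAGTCTGAGCGGGACCCGTCATATTTCCGGACTCTAGGCTCAGCTGG
>g1_s5
CAATGAATACCGAGCACTCCCTCCTAAGGAGATTTTTTGCTTGGATCTTGTAATTGACAAACCAGAACTACATGACCACTAGCGAATGCAAAGATGTACTTCATATTCGCGCGTACATACCTGGATGTGATGGGATTGCCAGCGAAGCTCGCCAGCCGGACCACGAACATACAGTATTCTGACACTACAGAACAATGTTCAAGGAGCTTATGTATATCTGGTGAAACCATCTGTAACACTCTCGGATAATCGGTATAGATCACGAAAAGTCTTAGCGGGACCCGTCATATTTCCGGACTCTAGGCTCAGCTGG
>g1_s6
CAATGAATACCGAGCACTCCCTCCTAAGGAGATTTTTTGCTTGGATCTTGTAATTGACAAACCAGAACTACATGACCACTAGCGAATGCAAAGATGTACTTCATATTCGCGCGTACATACCTGGATGTGATGGGATTGCCAGCGAAGCTCGCCAGCCGGACCACGAACATACAGTATTCTGACACCACAGAACAATGATCAAGGAGCTTATGTATATCTGGTGAAACCATCTGTAACACTCTCGGATAATCGGTATAGATCAAGAAAAGTCTTAGCGGGACCCGTCATATTTCCGGACTCTAGGCTCAGCTGG
>g2_s1
CAATGAATACCGAGTACTCCCTCCTAAGGACATTTTTTGCTTGGATCTTGTAATTGACAAACCAGAACTAGATGACAAGTCTCGAAGGCAAAGATGTAGTTCAAATTTGCGCGTACATACCTGGATGTGATGGGATTGCCAGCGAAGCTAGCCAGCCGGTCCACGAACATACAGTATTCTGACACCACAGAACAATGTTCAAGTAGCATATGTATATCATGTGAAACAATCTGTAACACTCACGGATAATCGGTATAGATCAAGAAACGTCTTAGCGGGACCCGTCATATGTCCGGACTCTAGGCTCAGCTGG
>g2_s2
CAATGAATACCGAGTACTCCCTCCTAAGGACATTTATTGCTTGGATCTTGTAATTGACAAACCAGAACTAGATGACAAGTCTCGAAGGCAAAGATCTAGTTCAAATTCGCGCGTACATACCTGGATGTGATGGGATTGCCAGCGAAGCTAGCCAGCCGGTCCACGAACATACAGGATTCTGACACCACAGAACAATGTTCAAGTAGCATATGTATATCATGTGAAACAATCTGTAACACTCACGGATAATCGGTATAGATCAAGAAACGTCTTAGCGGGACCCGTCATATGTCCGGACTCTAGGCTCAGCTGG
>g2_s3
CAATGAATACCGAGTACTCCCTCCTAAGGACATTTTTTGCTTGGATCTTGTAATTGACAAACCAGAACTAGATGACAACTCTCGAAGGCAAAGATGTAGTTCAAATTCGCGCGTACATACCTGGATGTGATGGGATTGCCAGCGAAGCTAGCCAGCCGGTCCACGAACATACAGTATTCTGACACCACAGAACAATGTTCACGTAGCATATGTATATCATGTGAAACAATCTGTAACACTCACGGATAATCGGTATAGATCAAGAAACGTCTTAGCGGGACCCGTCATATGTCCGGACTCTAGGCTCAGCTGG
>g2_s4
CAATGAATACCGAGTACTCCCTCCTAAGGACATTTTTTGCTTGGATCTTGTAATTGACAAACCAGAACTAGATGACAAGTCTCGAAGGCATAGATGTAGTTCAAATTCGCGCGTACATACCTGGATGTGATGGGATTGCCAGCGAAGCAAGCCAGCCGGTCCACGAACATACAGTATTCTGACACCACAGAACAATGTTCAAGTAGCATATGTATATCATGTGAAACAATCTGTAACACTCACGGATAATCGGTATAGATCAAGAAACTTCTTAGCGGGACCCGTCATATGTCCGGACTCTAGGCTCAGCTGG
>g2_s5
CAATGAATACCGAGTACTCCCTCCTAAGGACATTTTTTGCTTGGATGTTGTAATTGACAAACCAGAACTAGATGACAAGTCTCGAAGGCAAAGATGTAGTTCAAATTCGCGCGTACATACCTGGATGTGATGGGATTGCCAGCGAAGCTAGCCAGCCGGTCCACGAACATACAGTATTCTGACACCACAGAACAATGTTCAAGCAGCATATGTATATCATGTGAAACAATCTGTAACACTCACGGATTATCGGTATAGATCAAGAAACGTCTTAGCGGGACCCGTCATATGTCCGGACTCTAGGCTCAGCTGG
>g2_s6
CAATGAATACCGAGTACTCCCTCCTAAGGACATTTTTTGCTTGGATCTTGGAATTGACAAACCAGAACTAGATGACAAGTCTCGAAGGCAAAGATGTAGTTCAAATTCGCGCGTACATACCTGGATGTGATGGGATTGCCAGCGAAGCTAGCCAGCCAGTCCACGAACATACAGTATTCTGACACCACAGAACAATGTTCAAGTAGCATATGTATATCATGTGAAACAATCTGTAACACTCTCGGATAATCGGTATAGATCAAGAGACGTCTTAGCGGGACCCGTCATATGTCCGGACTCTAGGCTCAGCTGG
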