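HEADER    SYNTHETIC TOY STRUCTURE
REMARK    Hand-written desk-scale fixture: 3 protein atoms + 2 waters.
ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  GLY A   1       1.000   2.000   3.000  1.00  0.00           C
ATOM      3  O   GLY A   1       2.400   1.100  -0.500  1.00  0.00           O
HETATM    4  O   HOH A   2       5.000   5.000   5.000  1.00  0.00           O
HETATM    5  O   HOH A   3      -5.000   4.000   2.000  1.00  0.00           O
END
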