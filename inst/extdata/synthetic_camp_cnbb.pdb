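ATOM      1  CA  ALA A 360       1.200   0.800   0.000  1.00  0.00           C
ATOM      2  CB  ALA A 360       0.000   0.000   0.000  1.00  0.00           C
ATOM      3  CA  GLY A 355       3.100   4.000   1.500  1.00  0.00           C
ATOM      4  CA  LEU A 351       6.300   1.000   0.500  1.00  0.00           C
ATOM      5  CG  LEU A 351       4.900   0.000   0.000  1.00  0.00           C
ATOM      6  CA  GLY A 350       6.900   3.000   2.000  1.00  0.00           C
END
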