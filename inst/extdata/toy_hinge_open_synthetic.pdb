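ATOM      1  CA  GLU A   1       0.000   2.300   0.000  1.00  0.00           C
ATOM      2  CA  HIS A   2       1.500  -0.399   2.265  1.00  0.00           C
ATOM      3  CA  ALA A   3       3.000  -2.161  -0.787  1.00  0.00           C
ATOM      4  CA  CYS A   4       4.500   1.150  -1.992  1.00  0.00           C
ATOM      5  CA  MET A   5       6.000   1.762   1.478  1.00  0.00           C
ATOM      6  CA  GLN A   6       7.500  -1.762   1.478  1.00  0.00           C
ATOM      7  CA  VAL A   7       9.000  -1.150  -1.992  1.00  0.00           C
ATOM      8  CA  TRP A   8      10.500   2.161  -0.787  1.00  0.00           C
ATOM      9  CA  ALA A   9      12.000   0.399   2.265  1.00  0.00           C
ATOM     10  CA  LEU A  10      13.500  -2.300   0.000  1.00  0.00           C
ATOM     11  CA  GLN A  11      15.000   0.399  -2.265  1.00  0.00           C
ATOM     12  CA  LEU A  12      16.500   2.161   0.787  1.00  0.00           C
ATOM     13  CA  HIS A  13      18.000  -1.150   1.992  1.00  0.00           C
ATOM     14  CA  LYS A  14      19.500  -1.762  -1.478  1.00  0.00           C
ATOM     15  CA  ARG A  15      21.000   1.762  -1.478  1.00  0.00           C
ATOM     16  CA  PHE A  16      22.500   1.150   1.992  1.00  0.00           C
ATOM     17  CA  LYS A  17      24.000  -2.161   0.787  1.00  0.00           C
ATOM     18  CA  GLN A  18      25.500  -0.399  -2.265  1.00  0.00           C
ATOM     19  CA  PHE A  19      28.500  -1.000   1.700  1.00  0.00           C
ATOM     20  CA  PHE A  20      31.000   0.500   4.000  1.00  0.00           C
ATOM     21  CA  CYS A  21      33.500  -1.500   6.200  1.00  0.00           C
ATOM     22  CA  LEU A  22      33.500   2.000   6.700  1.00  0.00           C
ATOM     23  CA  ASN A  23      32.793  -0.736  10.855  1.00  0.00           C
ATOM     24  CA  ARG A  24      35.785  -2.790  12.077  1.00  0.00           C
ATOM     25  CA  ALA A  25      37.098   0.235  14.024  1.00  0.00           C
ATOM     26  CA  TYR A  26      33.650   0.740  15.611  1.00  0.00           C
ATOM     27  CA  ASP A  27      33.535  -2.958  16.598  1.00  0.00           C
ATOM     28  CA  GLY A  28      37.023  -2.677  18.154  1.00  0.00           C
ATOM     29  CA  LEU A  29      35.927   0.426  20.112  1.00  0.00           C
ATOM     30  CA  LEU A  30      32.819  -1.431  21.362  1.00  0.00           C
ATOM     31  CA  GLY A  31      34.995  -4.387  22.455  1.00  0.00           C
ATOM     32  CA  ARG A  32      37.347  -2.002  24.311  1.00  0.00           C
ATOM     33  CA  TYR A  33      34.354  -0.372  26.059  1.00  0.00           C
ATOM     34  CA  TYR A  34      33.041  -3.821  27.082  1.00  0.00           C
ATOM     35  CA  ASN A  35      36.490  -4.751  28.464  1.00  0.00           C
ATOM     36  CA  GLY A  36      36.605  -1.477  30.447  1.00  0.00           C
ATOM     37  CA  ILE A  37      33.117  -2.182  31.861  1.00  0.00           C
ATOM     38  CA  ASN A  38      34.213  -5.709  32.873  1.00  0.00           C
ATOM     39  CA  GLY A  39      37.321  -4.277  34.593  1.00  0.00           C
ATOM     40  CA  HIS A  40      35.145  -1.745  36.470  1.00  0.00           C
TER
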