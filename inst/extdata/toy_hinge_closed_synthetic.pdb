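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
ATOM     23  CA  ASN A  23      29.000   0.000   5.700  1.00  0.00           C
ATOM     24  CA  ARG A  24      27.500  -2.265   8.399  1.00  0.00           C
ATOM     25  CA  ALA A  25      26.000   0.787  10.161  1.00  0.00           C
ATOM     26  CA  TYR A  26      24.500   1.992   6.850  1.00  0.00           C
ATOM     27  CA  ASP A  27      23.000  -1.478   6.238  1.00  0.00           C
ATOM     28  CA  GLY A  28      21.500  -1.478   9.762  1.00  0.00           C
ATOM     29  CA  LEU A  29      20.000   1.992   9.150  1.00  0.00           C
ATOM     30  CA  LEU A  30      18.500   0.787   5.839  1.00  0.00           C
ATOM     31  CA  GLY A  31      17.000  -2.265   7.601  1.00  0.00           C
ATOM     32  CA  ARG A  32      15.500  -0.000  10.300  1.00  0.00           C
ATOM     33  CA  TYR A  33      14.000   2.265   7.601  1.00  0.00           C
ATOM     34  CA  TYR A  34      12.500  -0.787   5.839  1.00  0.00           C
ATOM     35  CA  ASN A  35      11.000  -1.992   9.150  1.00  0.00           C
ATOM     36  CA  GLY A  36       9.500   1.478   9.762  1.00  0.00           C
ATOM     37  CA  ILE A  37       8.000   1.478   6.238  1.00  0.00           C
ATOM     38  CA  ASN A  38       6.500  -1.992   6.850  1.00  0.00           C
ATOM     39  CA  GLY A  39       5.000  -0.787  10.161  1.00  0.00           C
ATOM     40  CA  HIS A  40       3.500   2.265   8.399  1.00  0.00           C
TER
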