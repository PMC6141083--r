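ATOM      1  N   MET A1606       0.000   0.000   0.000  1.00  0.00           N
ATOM      2  CA  MET A1606       1.460   0.000   0.000  1.00  0.00           C
ATOM      3  C   MET A1606       2.010   1.400   0.000  1.00  0.00           C
ATOM      4  O   MET A1606       1.300   2.410   0.000  1.00  0.00           O
ATOM      5  CB  MET A1606       1.960  -0.770   1.230  1.00  0.00           C
ATOM      6  CG  MET A1606       3.170  -1.650   1.050  1.00  0.00           C
ATOM      7  SD  MET A1606       3.700  -2.450   2.570  1.00  0.00           S
ATOM      8  CE  MET A1606       5.190  -3.280   2.000  1.00  0.00           C
ATOM      9  N   ALA A1607       3.210   1.650  -0.150  1.00  0.00           N
ATOM     10  CA  ALA A1607       4.000   2.880  -0.150  1.00  0.00           C
ATOM     11  C   ALA A1607       5.480   2.600  -0.300  1.00  0.00           C
ATOM     12  O   ALA A1607       6.300   3.520  -0.300  1.00  0.00           O
ATOM     13  CB  ALA A1607       3.770   3.720   1.100  1.00  0.00           C
END
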