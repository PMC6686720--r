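* Generic CHARMM-style parameter set for the beta-diamide model compounds.
* Synthetic idealized values (amide/aliphatic patterns); kcal/mol, Angstrom,
* degrees.  Backbone proper dihedral terms are supplied separately by the
* constraint system; wildcard rows below cover the remaining torsions.
BONDS
CT3  HA3   322.0  1.090
CTA1 HB1   309.0  1.090
CTA2 HB2   309.0  1.090
CTB1 HB1   309.0  1.090
CTB2 HB2   309.0  1.090
C    O     620.0  1.230
C    NH1   370.0  1.345
C    CT3   250.0  1.520
C    CTA2  250.0  1.522
C    CTB1  250.0  1.522
NH1  H     440.0  1.010
NH1  CT3   320.0  1.449
NH1  CTA1  320.0  1.455
NH1  CTB2  320.0  1.455
CTA1 CTA2  222.5  1.530
CTA2 CTB2  222.5  1.530
CTB1 CTB2  222.5  1.530
CTA1 CTB1  222.5  1.530
CT3  CTA1  222.5  1.530
CT3  CTB1  222.5  1.530
ANGLES
HA3  CT3  HA3   35.0 109.5
C    CT3  HA3   35.0 109.5
HA3  CT3  NH1   35.0 109.5
CTA1 CT3  HA3   35.0 109.5
CTB1 CT3  HA3   35.0 109.5
C    CTA2 HB2   35.0 109.5
C    CTB1 HB1   35.0 109.5
CT3  CTA1 HB1   35.0 109.5
CT3  CTB1 HB1   35.0 109.5
CTA1 CTA2 HB2   35.0 109.5
CTA1 CTB1 HB1   35.0 109.5
HB1  CTA1 CTB1  35.0 109.5
CTA2 CTA1 HB1   35.0 109.5
CTA2 CTB2 HB2   35.0 109.5
CTB1 CTB2 HB2   35.0 109.5
CTB2 CTA2 HB2   35.0 109.5
CTB2 CTB1 HB1   35.0 109.5
HB1  CTA1 NH1   35.0 109.5
HB2  CTA2 HB2   35.0 108.0
HB2  CTB2 HB2   35.0 108.0
HB2  CTB2 NH1   35.0 109.5
C    CTA2 CTA1  58.0 111.5
C    CTA2 CTB2  58.0 111.5
C    CTB1 CTA1  58.0 111.5
C    CTB1 CTB2  58.0 111.5
C    CTB1 CT3   58.0 111.0
CT3  CTA1 CTA2  58.0 111.0
CT3  CTA1 CTB1  58.0 111.0
CT3  CTB1 CTA1  58.0 111.0
CT3  CTB1 CTB2  58.0 111.0
CT3  CTA1 NH1   58.0 109.5
CTA2 CTA1 NH1   58.0 111.5
CTA2 CTB2 NH1   58.0 111.5
CTB1 CTB2 NH1   58.0 111.5
CTB1 CTA1 NH1   58.0 111.5
C    NH1  CT3   50.0 121.5
C    NH1  CTA1  50.0 121.5
C    NH1  CTB2  50.0 121.5
C    NH1  H     34.0 119.5
CT3  NH1  H     35.0 119.0
CTA1 NH1  H     35.0 119.0
CTB2 NH1  H     35.0 119.0
CT3  C    O     80.0 121.0
CT3  C    NH1   80.0 114.5
CTA2 C    O     80.0 121.0
CTB1 C    O     80.0 121.0
CTA2 C    NH1   80.0 116.5
CTB1 C    NH1   80.0 116.5
NH1  C    O     80.0 123.5
DIHEDRALS
X    C    NH1  X     2.50  2  180.0
X    CT3  C    X     0.05  3  180.0
X    CT3  NH1  X     0.00  3    0.0
X    CT3  CTA1 X     0.16  3    0.0
X    CT3  CTB1 X     0.16  3    0.0
X    NH1  CTA1 X     0.00  3    0.0
X    NH1  CTB2 X     0.00  3    0.0
X    CTA1 CTA2 X     0.00  3    0.0
X    CTA2 CTB2 X     0.00  3    0.0
X    CTB2 CTB1 X     0.00  3    0.0
X    CTA1 CTB1 X     0.00  3    0.0
X    CTA2 C    X     0.00  3    0.0
X    CTB1 C    X     0.00  3    0.0
NONBONDED
CT3   -0.078  2.040  -0.010  1.900
CTA1  -0.032  2.000  -0.010  1.900
CTA2  -0.056  2.010  -0.010  1.900
CTB1  -0.032  2.000  -0.010  1.900
CTB2  -0.056  2.010  -0.010  1.900
C     -0.110  2.000
O     -0.120  1.700
NH1   -0.200  1.850
H     -0.046  0.2245
HA3   -0.024  1.340
HB1   -0.022  1.320
HB2   -0.028  1.340
END
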