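* beta23 model diamide: Ac-(2S,3S)b23h(2Ala,3Ala)-NHMe (methyls on both
* backbone carbons).  Idealized internal-coordinate build; partial charges
* are synthetic placeholders following the usual amide/aliphatic pattern.
RESI BL23 0.00
ATOM CAY  CT3  -0.27
ATOM HY1  HA3   0.09
ATOM HY2  HA3   0.09
ATOM HY3  HA3   0.09
ATOM CY   C     0.51
ATOM OY   O    -0.51
ATOM N    NH1  -0.47
ATOM HN   H     0.31
ATOM CB   CTA1 -0.01
ATOM HB   HB1   0.09
ATOM CG1  CT3  -0.27
ATOM HG11 HA3   0.09
ATOM HG12 HA3   0.09
ATOM HG13 HA3   0.09
ATOM CA   CTB1 -0.01
ATOM HA   HB1   0.09
ATOM CG2  CT3  -0.27
ATOM HG21 HA3   0.09
ATOM HG22 HA3   0.09
ATOM HG23 HA3   0.09
ATOM C    C     0.51
ATOM O    O    -0.51
ATOM NT   NH1  -0.47
ATOM HNT  H     0.31
ATOM CAT  CT3  -0.11
ATOM HT1  HA3   0.09
ATOM HT2  HA3   0.09
ATOM HT3  HA3   0.09
BOND CAY HY1
BOND CAY HY2
BOND CAY HY3
BOND CAY CY
BOND CY  OY
BOND CY  N
BOND N   HN
BOND N   CB
BOND CB  HB
BOND CB  CG1
BOND CG1 HG11
BOND CG1 HG12
BOND CG1 HG13
BOND CB  CA
BOND CA  HA
BOND CA  CG2
BOND CG2 HG21
BOND CG2 HG22
BOND CG2 HG23
BOND CA  C
BOND C   O
BOND C   NT
BOND NT  HNT
BOND NT  CAT
BOND CAT HT1
BOND CAT HT2
BOND CAT HT3
BACKBONE CY N CB CA C NT
TORS phi   CY N CB CA
TORS theta N CB CA C
TORS psi   CB CA C NT
CHIR CB S
CHIR CA S
FREE mey met meg1 meg2
VAR phi   -140
VAR theta   60
VAR psi   -135
VAR mey     60
VAR met     60
VAR meg1    60
VAR meg2    60
BUILD CAY  -    -    -   0.000   0.0    0
BUILD CY   CAY  -    -   1.520   0.0    0
BUILD OY   CY   CAY  -   1.229 121.0    0
BUILD N    CY   CAY  OY  1.345 114.5  180
BUILD CB   N    CY   CAY 1.455 121.5  180
BUILD HN   N    CY   CAY 1.010 119.5    0
BUILD HY1  CAY  CY   N   1.090 109.5  @mey
BUILD HY2  CAY  CY   N   1.090 109.5  @mey+120
BUILD HY3  CAY  CY   N   1.090 109.5  @mey-120
BUILD CA   CB   N    CY  1.530 111.5  @phi
BUILD CG1  CB   N    CY  1.530 109.5  @phi-120
BUILD HB   CB   N    CY  1.090 109.5  @phi+120
BUILD HG11 CG1  CB   N   1.090 109.5  @meg1
BUILD HG12 CG1  CB   N   1.090 109.5  @meg1+120
BUILD HG13 CG1  CB   N   1.090 109.5  @meg1-120
BUILD C    CA   CB   N   1.522 111.5  @theta
BUILD CG2  CA   CB   N   1.530 109.5  @theta-120
BUILD HA   CA   CB   N   1.090 109.5  @theta+120
BUILD HG21 CG2  CA   CB  1.090 109.5  @meg2
BUILD HG22 CG2  CA   CB  1.090 109.5  @meg2+120
BUILD HG23 CG2  CA   CB  1.090 109.5  @meg2-120
BUILD NT   C    CA   CB  1.345 116.5  @psi
BUILD O    C    CA   CB  1.229 121.0  @psi+180
BUILD CAT  NT   C    CA  1.449 121.5  180
BUILD HNT  NT   C    CA  1.010 119.5    0
BUILD HT1  CAT  NT   C   1.090 109.5  @met
BUILD HT2  CAT  NT   C   1.090 109.5  @met+120
BUILD HT3  CAT  NT   C   1.090 109.5  @met-120
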