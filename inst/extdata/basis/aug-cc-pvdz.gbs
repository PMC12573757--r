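! aug-cc-pVDZ for H, N, O (Gaussian94 exchange text format).
! This file is intended for use UNCONTRACTED (the package drops contraction
! coefficients and promotes every distinct primitive to its own shell, so
! only the exponents below enter any computed quantity).  Contraction
! coefficients of the inner N/O s blocks are nominal.
****
H     0
S   4   1.00
     13.0100000          0.0196850
      1.9620000          0.1379770
      0.4446000          0.4781480
      0.1220000          0.5012400
S   1   1.00
      0.1220000          1.0000000
S   1   1.00
      0.0297400          1.0000000
P   1   1.00
      0.7270000          1.0000000
P   1   1.00
      0.1410000          1.0000000
****
N     0
S   8   1.00
   9046.0000000          0.0007000
   1357.0000000          0.0053890
    309.3000000          0.0274060
     87.7300000          0.1032070
     28.5600000          0.2787230
     10.2100000          0.4485400
      3.8380000          0.2782380
      0.7466000          0.0154400
S   8   1.00
   9046.0000000         -0.0001530
   1357.0000000         -0.0012080
    309.3000000         -0.0059920
     87.7300000         -0.0245440
     28.5600000         -0.0674590
     10.2100000         -0.1580780
      3.8380000         -0.1218310
      0.7466000          0.5490030
S   1   1.00
      0.2248000          1.0000000
S   1   1.00
      0.0612400          1.0000000
P   3   1.00
     13.5500000          0.0399190
      2.9170000          0.2171690
      0.7973000          0.5103190
P   1   1.00
      0.2185000          1.0000000
P   1   1.00
      0.0561100          1.0000000
D   1   1.00
      0.8170000          1.0000000
D   1   1.00
      0.2300000          1.0000000
****
O     0
S   8   1.00
  11720.0000000          0.0007100
   1759.0000000          0.0054700
    400.8000000          0.0278370
    113.7000000          0.1048000
     37.0300000          0.2830620
     13.2700000          0.4487190
      5.0250000          0.2709520
      1.0130000          0.0154580
S   8   1.00
  11720.0000000         -0.0001600
   1759.0000000         -0.0012630
    400.8000000         -0.0062670
    113.7000000         -0.0257160
     37.0300000         -0.0709240
     13.2700000         -0.1654110
      5.0250000         -0.1169550
      1.0130000          0.5573680
S   1   1.00
      0.3023000          1.0000000
S   1   1.00
      0.0789600          1.0000000
P   3   1.00
     17.7000000          0.0430180
      3.8540000          0.2289130
      1.0460000          0.5087280
P   1   1.00
      0.2753000          1.0000000
P   1   1.00
      0.0685600          1.0000000
D   1   1.00
      1.1850000          1.0000000
D   1   1.00
      0.3320000          1.0000000
****
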