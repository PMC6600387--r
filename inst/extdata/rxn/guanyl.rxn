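$RXN
guanyl addition by Cys
  covbench

  2  1
$MOL
guanidine
  covbench

  4  3  0  0  0  0  0  0  0  0999 V2000
    1.3000    0.4000    0.0000 N   0  0  0  0  0  0  0  0  0  1  0  0
    2.6000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  2  0  0
    3.9000    0.4000    0.0000 N   0  0  0  0  0  0  0  0  0  3  0  0
    5.2000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  4  0  0
  1  2  2  0
  2  3  1  0
  2  4  1  0
M  END
$MOL
nucleophile-S
  covbench

  1  0  0  0  0  0  0  0  0  0999 V2000
    1.3000    0.4000    0.0000 S   0  0  0  0  0  0  0  0  0 99  0  0
M  END
$MOL
thio adduct
  covbench

  5  4  0  0  0  0  0  0  0  0999 V2000
    1.3000    0.4000    0.0000 N   0  0  0  0  0  0  0  0  0  1  0  0
    2.6000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  2  0  0
    3.9000    0.4000    0.0000 N   0  0  0  0  0  0  0  0  0  3  0  0
    5.2000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  4  0  0
    6.5000    0.4000    0.0000 S   0  0  0  0  0  0  0  0  0 99  0  0
  1  2  1  0
  2  3  1  0
  2  4  1  0
  2  5  1  0
M  END
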