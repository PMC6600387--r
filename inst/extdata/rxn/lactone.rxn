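$RXN
lactone opening by Ser
  covbench

  2  1
$MOL
gamma-lactone
  covbench

  6  6  0  0  0  0  0  0  0  0999 V2000
    1.3000    0.4000    0.0000 C   0  0  0  0  0  0  0  0  0  1  0  0
    2.6000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  2  0  0
    3.9000    0.4000    0.0000 O   0  0  0  0  0  0  0  0  0  3  0  0
    5.2000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  4  0  0
    6.5000    0.4000    0.0000 C   0  0  0  0  0  0  0  0  0  5  0  0
    7.8000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  6  0  0
  1  2  2  0
  1  3  1  0
  3  4  1  0
  4  5  1  0
  5  6  1  0
  6  1  1  0
M  END
$MOL
nucleophile-O
  covbench

  1  0  0  0  0  0  0  0  0  0999 V2000
    1.3000    0.4000    0.0000 O   0  0  0  0  0  0  0  0  0 99  0  0
M  END
$MOL
ring-opened ester
  covbench

  7  6  0  0  0  0  0  0  0  0999 V2000
    1.3000    0.4000    0.0000 C   0  0  0  0  0  0  0  0  0  1  0  0
    2.6000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  2  0  0
    3.9000    0.4000    0.0000 O   0  0  0  0  0  0  0  0  0  3  0  0
    5.2000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  4  0  0
    6.5000    0.4000    0.0000 C   0  0  0  0  0  0  0  0  0  5  0  0
    7.8000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  6  0  0
    9.1000    0.4000    0.0000 O   0  0  0  0  0  0  0  0  0 99  0  0
  1  2  2  0
  3  4  1  0
  4  5  1  0
  5  6  1  0
  6  1  1  0
  1  7  1  0
M  END
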