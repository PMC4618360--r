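channels:
- Fp1
- Fpz
- Fp2
- AF7
- AF3
- AFz
- AF4
- AF8
- F7
- F5
- F3
- F1
- Fz
- F2
- F4
- F6
- F8
- FT7
- FC5
- FC3
- FC1
- FCz
- FC2
- FC4
- FC6
- FT8
- T7
- C5
- C3
- C1
- Cz
- C2
- C4
- C6
- T8
- TP7
- CP5
- CP3
- CP1
- CPz
- CP2
- CP4
- CP6
- TP8
- P7
- P5
- P3
- P1
- Pz
- P2
- P4
- P6
- P8
- PO7
- PO3
- POz
- PO4
- PO8
- O1
- Oz
- O2
positions:
  Fp1:
  - -1.0
  - 4.0
  Fpz:
  - 0.0
  - 4.0
  Fp2:
  - 1.0
  - 4.0
  AF7:
  - -2.0
  - 3.0
  AF3:
  - -1.0
  - 3.0
  AFz:
  - 0.0
  - 3.0
  AF4:
  - 1.0
  - 3.0
  AF8:
  - 2.0
  - 3.0
  F7:
  - -4.0
  - 2.0
  F5:
  - -3.0
  - 2.0
  F3:
  - -2.0
  - 2.0
  F1:
  - -1.0
  - 2.0
  Fz:
  - 0.0
  - 2.0
  F2:
  - 1.0
  - 2.0
  F4:
  - 2.0
  - 2.0
  F6:
  - 3.0
  - 2.0
  F8:
  - 4.0
  - 2.0
  FT7:
  - -4.0
  - 1.0
  FC5:
  - -3.0
  - 1.0
  FC3:
  - -2.0
  - 1.0
  FC1:
  - -1.0
  - 1.0
  FCz:
  - 0.0
  - 1.0
  FC2:
  - 1.0
  - 1.0
  FC4:
  - 2.0
  - 1.0
  FC6:
  - 3.0
  - 1.0
  FT8:
  - 4.0
  - 1.0
  T7:
  - -4.0
  - 0.0
  C5:
  - -3.0
  - 0.0
  C3:
  - -2.0
  - 0.0
  C1:
  - -1.0
  - 0.0
  Cz:
  - 0.0
  - 0.0
  C2:
  - 1.0
  - 0.0
  C4:
  - 2.0
  - 0.0
  C6:
  - 3.0
  - 0.0
  T8:
  - 4.0
  - 0.0
  TP7:
  - -4.0
  - -1.0
  CP5:
  - -3.0
  - -1.0
  CP3:
  - -2.0
  - -1.0
  CP1:
  - -1.0
  - -1.0
  CPz:
  - 0.0
  - -1.0
  CP2:
  - 1.0
  - -1.0
  CP4:
  - 2.0
  - -1.0
  CP6:
  - 3.0
  - -1.0
  TP8:
  - 4.0
  - -1.0
  P7:
  - -4.0
  - -2.0
  P5:
  - -3.0
  - -2.0
  P3:
  - -2.0
  - -2.0
  P1:
  - -1.0
  - -2.0
  Pz:
  - 0.0
  - -2.0
  P2:
  - 1.0
  - -2.0
  P4:
  - 2.0
  - -2.0
  P6:
  - 3.0
  - -2.0
  P8:
  - 4.0
  - -2.0
  PO7:
  - -2.0
  - -3.0
  PO3:
  - -1.0
  - -3.0
  POz:
  - 0.0
  - -3.0
  PO4:
  - 1.0
  - -3.0
  PO8:
  - 2.0
  - -3.0
  O1:
  - -1.0
  - -4.0
  Oz:
  - 0.0
  - -4.0
  O2:
  - 1.0
  - -4.0
neighbors:
  Fp1:
  - Fpz
  - AF3
  Fpz:
  - Fp1
  - Fp2
  - AFz
  Fp2:
  - Fpz
  - AF4
  AF7:
  - AF3
  - F3
  AF3:
  - AF7
  - AFz
  - Fp1
  - F1
  AFz:
  - AF3
  - AF4
  - Fpz
  - Fz
  AF4:
  - AFz
  - AF8
  - Fp2
  - F2
  AF8:
  - AF4
  - F4
  F7:
  - F5
  - FT7
  F5:
  - F7
  - F3
  - FC5
  F3:
  - F5
  - F1
  - AF7
  - FC3
  F1:
  - F3
  - Fz
  - AF3
  - FC1
  Fz:
  - F1
  - F2
  - AFz
  - FCz
  F2:
  - Fz
  - F4
  - AF4
  - FC2
  F4:
  - F2
  - F6
  - AF8
  - FC4
  F6:
  - F4
  - F8
  - FC6
  F8:
  - F6
  - FT8
  FT7:
  - FC5
  - F7
  - T7
  FC5:
  - FT7
  - FC3
  - F5
  - C5
  FC3:
  - FC5
  - FC1
  - F3
  - C3
  FC1:
  - FC3
  - FCz
  - F1
  - C1
  FCz:
  - FC1
  - FC2
  - Fz
  - Cz
  FC2:
  - FCz
  - FC4
  - F2
  - C2
  FC4:
  - FC2
  - FC6
  - F4
  - C4
  FC6:
  - FC4
  - FT8
  - F6
  - C6
  FT8:
  - FC6
  - F8
  - T8
  T7:
  - C5
  - FT7
  - TP7
  C5:
  - T7
  - C3
  - FC5
  - CP5
  C3:
  - C5
  - C1
  - FC3
  - CP3
  C1:
  - C3
  - Cz
  - FC1
  - CP1
  Cz:
  - C1
  - C2
  - FCz
  - CPz
  C2:
  - Cz
  - C4
  - FC2
  - CP2
  C4:
  - C2
  - C6
  - FC4
  - CP4
  C6:
  - C4
  - T8
  - FC6
  - CP6
  T8:
  - C6
  - FT8
  - TP8
  TP7:
  - CP5
  - T7
  - P7
  CP5:
  - TP7
  - CP3
  - C5
  - P5
  CP3:
  - CP5
  - CP1
  - C3
  - P3
  CP1:
  - CP3
  - CPz
  - C1
  - P1
  CPz:
  - CP1
  - CP2
  - Cz
  - Pz
  CP2:
  - CPz
  - CP4
  - C2
  - P2
  CP4:
  - CP2
  - CP6
  - C4
  - P4
  CP6:
  - CP4
  - TP8
  - C6
  - P6
  TP8:
  - CP6
  - T8
  - P8
  P7:
  - P5
  - TP7
  P5:
  - P7
  - P3
  - CP5
  P3:
  - P5
  - P1
  - CP3
  - PO7
  P1:
  - P3
  - Pz
  - CP1
  - PO3
  Pz:
  - P1
  - P2
  - CPz
  - POz
  P2:
  - Pz
  - P4
  - CP2
  - PO4
  P4:
  - P2
  - P6
  - CP4
  - PO8
  P6:
  - P4
  - P8
  - CP6
  P8:
  - P6
  - TP8
  PO7:
  - PO3
  - P3
  PO3:
  - PO7
  - POz
  - P1
  - O1
  POz:
  - PO3
  - PO4
  - Pz
  - Oz
  PO4:
  - POz
  - PO8
  - P2
  - O2
  PO8:
  - PO4
  - P4
  O1:
  - Oz
  - PO3
  Oz:
  - O1
  - O2
  - POz
  O2:
  - Oz
  - PO4
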