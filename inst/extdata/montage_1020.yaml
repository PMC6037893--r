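labels:
- Fp2
- Fp1
- F8
- F7
- F4
- F3
- A2
- A1
- T4
- T3
- C4
- C3
- T6
- T5
- P4
- P3
- O2
- O1
- Fz
- Cz
- Pz
neighbors:
  Fp2:
  - Fp1
  - F8
  - F4
  - Fz
  Fp1:
  - Fp2
  - F7
  - F3
  - Fz
  F8:
  - Fp2
  - F4
  - T4
  - A2
  F7:
  - Fp1
  - F3
  - T3
  - A1
  F4:
  - Fp2
  - F8
  - Fz
  - C4
  F3:
  - Fp1
  - F7
  - Fz
  - C3
  A2:
  - F8
  - T4
  - T6
  A1:
  - F7
  - T3
  - T5
  T4:
  - F8
  - C4
  - T6
  - A2
  T3:
  - F7
  - C3
  - T5
  - A1
  C4:
  - F4
  - T4
  - Cz
  - P4
  C3:
  - F3
  - T3
  - Cz
  - P3
  T6:
  - T4
  - P4
  - O2
  - A2
  T5:
  - T3
  - P3
  - O1
  - A1
  P4:
  - C4
  - T6
  - Pz
  - O2
  P3:
  - C3
  - T5
  - Pz
  - O1
  O2:
  - T6
  - P4
  - Pz
  - O1
  O1:
  - T5
  - P3
  - Pz
  - O2
  Fz:
  - Fp1
  - Fp2
  - F3
  - F4
  - Cz
  Cz:
  - Fz
  - C3
  - C4
  - Pz
  Pz:
  - Cz
  - P3
  - P4
  - O1
  - O2
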