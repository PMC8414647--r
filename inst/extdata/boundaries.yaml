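IGHV1-8*01:
  frame: 0
  regions:
    FR1:
    - 0
    - 18
    CDR1:
    - 18
    - 30
    FR2:
    - 30
    - 48
    CDR2:
    - 48
    - 60
    FR3:
    - 60
    - 81
IGHV3-23*01:
  frame: 0
  regions:
    FR1:
    - 0
    - 18
    CDR1:
    - 18
    - 30
    FR2:
    - 30
    - 48
    CDR2:
    - 48
    - 60
    FR3:
    - 60
    - 81
IGHV4-59*01:
  frame: 0
  regions:
    FR1:
    - 0
    - 18
    CDR1:
    - 18
    - 30
    FR2:
    - 30
    - 48
    CDR2:
    - 48
    - 60
    FR3:
    - 60
    - 81
IGHD3-10*01:
  frame: 0
  regions: []
IGHD2-2*01:
  frame: 0
  regions: []
IGHJ4*01:
  frame: 0
  regions:
    FR4:
    - 18
    - 30
IGHJ6*01:
  frame: 0
  regions:
    FR4:
    - 18
    - 30
IGHM*01:
  frame: 0
  regions: []
IGHG1*01:
  frame: 0
  regions: []
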