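bamt:
  CS_B:
    short: 0.9
    long: 0.1
  simpleGPC:
    short: 0.85
    long: 0.15
  SR:
    short: 0.9
    long: 0.1
blaf:
  CS_B:
    short: 0.2
    long: 0.8
  simpleGPC:
    short: 0.85
    long: 0.15
  SR:
    short: 0.15
    long: 0.85
blagd:
  CS_B:
    short: 0.05
    long: 0.95
  simpleGPC:
    short: 0.85
    long: 0.15
  SR:
    short: 0.9
    long: 0.1
git:
  CS_B:
    short: 0.95
    long: 0.05
  simpleGPC:
    short: 0.85
    long: 0.15
  SR:
    short: 0.15
    long: 0.85
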