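hact:
  CS_B:
    ae: 0.88
    open_o: 0.04
    long_o: 0.04
  CS_O:
    ae: 0.88
    open_o: 0.04
    long_o: 0.04
  simpleGPC:
    ae: 0.88
    open_o: 0.04
    long_o: 0.04
kalt:
  CS_B:
    ae: 0.15
    open_o: 0.06
    long_o: 0.75
  CS_O:
    ae: 0.88
    open_o: 0.04
    long_o: 0.04
  simpleGPC:
    ae: 0.88
    open_o: 0.04
    long_o: 0.04
wact:
  CS_B:
    ae: 0.88
    open_o: 0.04
    long_o: 0.04
  CS_O:
    ae: 0.12
    open_o: 0.8
    long_o: 0.04
  simpleGPC:
    ae: 0.88
    open_o: 0.04
    long_o: 0.04
wald:
  CS_B:
    ae: 0.15
    open_o: 0.06
    long_o: 0.75
  CS_O:
    ae: 0.12
    open_o: 0.8
    long_o: 0.04
  simpleGPC:
    ae: 0.88
    open_o: 0.04
    long_o: 0.04
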