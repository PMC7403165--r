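language_mode: english_style
conditions:
- hact
- wact
- kalt
- wald
response_categories:
- ae
- open_o
- long_o
rule_types:
- simpleGPC
- CS_O
- CS_B
items_per_condition:
  hact: 18
  wact: 18
  kalt: 18
  wald: 18
other_categories:
- other_vowel
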