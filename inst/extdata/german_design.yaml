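language_mode: german_style
conditions:
- bamt
- git
- blagd
- blaf
response_categories:
- short
- long
rule_types:
- simpleGPC
- SR
- CS_B
items_per_condition:
  bamt: 16
  git: 16
  blagd: 16
  blaf: 16
other_categories: []
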