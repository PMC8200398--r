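# Gastrointestinal protease panel: concerted pepsin + trypsin + chymotrypsin.
# P1 = residues cut after; p1prime_exclusions = residues that block the cut
# when they immediately follow the bond (empty here).
name: gi_default
rules:
  - enzyme_name: pepsin (pH 1.3)
    ec_number: 3.4.23.1
    p1: ["F", "L"]
    p1prime_exclusions: []
  - enzyme_name: trypsin
    ec_number: 3.4.21.4
    p1: ["K", "R"]
    p1prime_exclusions: []
  - enzyme_name: chymotrypsin
    ec_number: 3.4.21.1
    p1: ["F", "Y", "W", "N", "H"]
    p1prime_exclusions: []
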