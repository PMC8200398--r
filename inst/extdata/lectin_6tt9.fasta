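>lectin_6tt9 Phaseolus acutifolius seed lectin, recombinant construct (PDB 6TT9)
EAEAAASANDISFNFQRFNETNLILQGDASVSSSGQLRLTNLNDNGEPTLSSLGRAFYST
PIQIWDSTTGAVASFATSFTFNIRVPNNAGPADGLAFALVPVGSKPKDRGGLLGLFDGSD
SKAHTVAVEFDTLYNRDWDPRERHIGIDVNSIKSIKTTPWDFVNGEDAEVLITYDSSTKL
LVASLVYPSQKTSFIVSDTVDLKSVLPEWVSVGFSATSGISKGNVETNDLLSWSFASKLS
DGTTSEGLNHHHHHH
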