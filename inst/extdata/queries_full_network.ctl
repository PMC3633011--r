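# CTL queries for the full 111-place ErbB2/TLR2 network, in this package's
# query grammar. The renderings these were transcribed from contain
# unbalanced parentheses and fused tokens; the readings below are repaired
# interpretations, not verbatim transcriptions. They are runnable only against the
# full network with a small integer initial marking (the reachability
# graph at realistic markings is intractable); scaled-down instantiations
# on the simplified demo net ship with the test suite.

# Reachability: growth-factor stimulation can lead to at least one active
# PI3K-recruiting complex.
EF((HER2:Pi3k > 0) | (TLR:Pi3k > 0) | (TLR:MyD88:Pi3k > 0) | (H2:Gr:Gab:Pi3k > 0) | (Ras:GT:Pi3k > 0) | (ERBB3:ERBB2:Gr:Ga:Pi3k > 0) | (ERBB1:ERBB2:Gr:Ga:Pi3k > 0))

# Pathway: whenever Akt is engaged with Pdk1, mTOR (TORC2) is available or
# already complexed with it.
AG(P3Akt:Pdk1 != 0 => (TO2 != 0 | (P3:Akt:Pdk1:TO2 > 0)))

# Steady state: the system cycles with respect to the presence of Pten.
EG((Pten => EF !Pten) & (!Pten => EF Pten))
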