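# Curated E. coli RNA polymerase domain definitions (author residue numbering).
#
# These ranges are CURATED DATA, not code constants: they approximate the
# swivel-module decomposition used in the bacterial RNAP swiveling literature
# (clamp, dock, shelf, jaw, SI3 and the beta' C-terminal region move as a
# rigid body relative to the core module during pausing-associated swiveling).
# Exact boundaries vary between studies; override per structure when needed.
#
# Chains follow the usual E. coli EC deposition convention:
#   A/B = alpha, C = beta, D = beta', E = omega
# i.e. beta' ranges below are on chain D, beta ranges on chain C.

[domain.core]
select = "C:30-820 D:420-770"

[domain.clamp]
select = "D:3-342"

[domain.dock]
select = "D:370-419"

[domain.shelf]
select = "D:787-931"

[domain.SI3]
select = "D:943-1130"

[domain.jaw]
select = "D:1135-1317"

[domain.betaprime_cterm]
select = "D:1318-1407"

[domain.lid]
select = "D:251-264"

[domain.ZBD]
select = "D:49-88"

[domain.bridge_helix]
select = "D:770-805"

[domain.flap_tip]
select = "C:890-914"
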