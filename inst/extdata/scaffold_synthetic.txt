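# Designer-PPR scaffold data (SYNTHETIC STAND-IN).
#
# template: the 35-residue consensus-style repeat. Positions 5 and 35 are
#   the programmable code slots (the letters stored there are placeholders
#   and are always overwritten at design time); position 2 is the
#   hydrophobic clamp valine and position 13 the phosphate-binding lysine.
#   Helix a spans residues 1-14, helix b 17-30, followed by a short loop.
# ntd / ctd: helical capping domains fused to the repeat array to keep
#   designer constructs soluble (the natural caps come from maize PPR10).
#   These particular sequences are synthetic consensus-style stand-ins
#   with the correct architecture and lengths (NTD 51 aa, CTD 49 aa, so a
#   10-repeat construct is 450 aa and an offset of 122 places the repeats
#   at residues 174-523 as in the deposited crystal constructs); they are
#   NOT the literal natural sequences. Replace this file via
#   default_scaffold(path=...) to use real cap sequences.
template	VVTYNTLIDGLCKAGKVDEALELFEEMKEKGIKPD
ntd	MGSLSPQELAEAWRRFAELQDPSRLPHLLERWSAELNGQLPREAFDAWLRG
ctd	EWQALRPHLSEAWGRFQELAPDNPQRLAEHWPSLREQFGALSPEDWARH
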