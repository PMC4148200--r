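label: mel_original
species: D. melanogaster
sna_arc_pct: 21.0
final_cycle: 14.0
El: 245.0
Er: 90.0
Eh: 31.0
Tn: 6000.0
R: 15340.0
S: 4052.0
xi: 2.38
Gamma: 0.03
k_i: 1.97
k_e: 0.44
P_Cact: 50.0
k_Deg: 1.36
k_b: 0.02
Dl0: 36.0
DlCact0: 30.0
Cact0: 36.0
r: 3.08
'n': 100.0
t: 65.0
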