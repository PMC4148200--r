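label: dl_het_2
species: D. melanogaster (dl-/dl+)
sna_arc_pct: 21.0
final_cycle: 14.0
El: 241.5
Er: 102.4
Eh: 25.0
Tn: 6000.0
R: 15000.0
S: 4000.0
xi: 2.5
Gamma: 2.0
k_i: 4.0
k_e: 1.0
P_Cact: 50.0
k_Deg: 4.0
k_b: 0.02
Dl0: 18.0
DlCact0: 15.0
Cact0: 36.0
r: 3.08
'n': 92.0
t: 65.0
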