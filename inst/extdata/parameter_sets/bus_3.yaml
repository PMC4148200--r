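label: bus_3
species: D. busckii
sna_arc_pct: 17.0
final_cycle: 14.0
El: 189.0
Er: 93.4
Eh: 23.4
Tn: 6000.0
R: 12142.0
S: 4000.0
xi: 2.5
Gamma: 2.0
k_i: 4.0
k_e: 1.0
P_Cact: 50.0
k_Deg: 0.33
k_b: 0.02
Dl0: 36.0
DlCact0: 30.0
Cact0: 36.0
r: 2.0
'n': 86.0
t: 65.0
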