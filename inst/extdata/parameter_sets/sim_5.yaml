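label: sim_5
species: D. simulans
sna_arc_pct: 27.0
final_cycle: 14.0
El: 236.0
Er: 102.5
Eh: 30.1
Tn: 6000.0
R: 19285.0
S: 4000.0
xi: 2.5
Gamma: 2.0
k_i: 4.0
k_e: 0.5
P_Cact: 50.0
k_Deg: 2.0
k_b: 0.015
Dl0: 36.0
DlCact0: 30.0
Cact0: 36.0
r: 2.75
'n': 98.0
t: 65.0
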