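rule_id	name	smarts
urea	urea N-C(=O)	[#7;+0;!D1:1]-!@[C:2](=O)[#7;+0]
amide	amide C(=O)-N	[C;$(C=O):1](=O)-!@[#7;+0;!D1:2]
ester	ester C(=O)-O	[C;$(C=O):1](=O)-!@[O;D2;+0:2]
lactam_n_aliph_c	lactam N - aliphatic C	[N;R;+0;$(N(-C(=O))):1]-!@[C:2]
sulfonamide	sulfonamide N-S(=O)2	[#7;+0;!D1:1]-!@[S;$(S(=O)=O):2]
quaternary_n	quaternary N - C	[N;+1;D4:1]-!@[C:2]
arom_n_aliph_c	aromatic N - aliphatic C	[n;+0:1]-!@[C:2]
amine	amine N-C	[N;+0;!D1;!$(N=*);!$(N-C=[O,N,S]);!$(N-S(=O)=O):1]-!@[C:2]
ether	ether C-O	[C,c:1]-!@[O;D2;+0;!$(O-C=O):2]
olefin	olefin C=C	[C:1]=!@[C:2]
arom_c_arom_c	aromatic C - aromatic C	[c:1]-!@[c:2]
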