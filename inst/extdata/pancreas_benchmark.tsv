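Hes1	Neurog3
Hnf4a	Tcf1
Pdx1	Gck
Pdx1	Hnf4a
Pdx1	Iapp
Pdx1	Ins2
Pdx1	Nr5a2
Mafb	Ins2
Mafb	Pdx1
Neurog3	Nkx2-2
Nkx2-2	Gck
Nkx2-2	Iapp
Nkx2-2	Ins2
Onecut1	Pdx1
Onecut1	Neurog3
Onecut1	Tcf1
Pax6	Gck
Pax6	Iapp
Pax6	Ins2
Pax6	Pdx1
Tcf1	Hnf4a
Tcf1	Pdx1
Tcf1	Pklr
Tcf1	Slc2a2
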