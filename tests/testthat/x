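chain,resseq,resname,curvature,torsion,arc_length,writhe
A,1,ALA,0.140480631903109,0.0188846530662527,0,
A,2,ALA,0.306354434760684,0.150783563038312,4.60016460206485,
A,3,ALA,0.511407035755849,0.103764008221972,8.70438057893468,0.234895667775826
A,4,ALA,0.470317494352048,0.108174024910671,12.8697682997356,0.234928132230561
A,5,ALA,0.453465441685395,0.111016218782632,17.0714946717431,0.234898384958993
A,6,ALA,0.453465441685395,0.11101621878263,21.2743510145087,0.234898384958993
A,7,ALA,0.470317494352048,0.108174024910666,25.4760773865161,0.234928132230561
A,8,ALA,0.511407035755848,0.103764008221962,29.6414651073171,0.234895667775826
A,9,ALA,0.306354434760683,0.150783563038291,33.7456810841869,
A,10,ALA,0.140480631903077,0.0188846530666284,38.3458456862517,
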