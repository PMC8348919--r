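compound_id,qfit,docking_score,mw,fraction_csp3,rotatable_bonds,tpsa,gi_absorption,bbb_permeant,cyp1a2,cyp2c19,cyp2c9,cyp2d6,cyp3a4,lipinski_violations,sa_score
VS12,NA,10.62,375.4,0.30,4,113.4,High,No,Yes,No,No,No,No,0,3.40
VS16,NA,11.87,417.39,0.09,7,105.7,High,No,No,Yes,No,No,No,0,3.32
VS19,NA,10.76,401.44,0.22,8,98.6,High,No,Yes,No,No,No,No,0,3.25
VS26,NA,11.03,429.4,0.35,9,130.3,High,No,No,Yes,No,No,No,0,3.34
Febuxostat,NA,8.22,316.37,0.31,5,111.5,High,No,Yes,Yes,Yes,No,No,0,3.12
44,NA,10.69,310.31,0.12,5,122.9,High,No,No,No,No,No,No,0,2.64
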