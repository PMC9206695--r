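compound,is_straight_chain_saturated_alkan1ol,carbon_count
Phenylethyl Alcohol,FALSE,8
2-methyl-1-Propanol,FALSE,4
3-methyl-1-Butanol,FALSE,5
2-phenoxy-Ethanol,FALSE,8
1-Triacontanol,TRUE,30
1-Hexacosanol,TRUE,26
1-Dodecanol,TRUE,12
1-Hexadecanol,TRUE,16
2-O-decyl-Threitol,FALSE,14
2-ethyl-2-methyl-Tridecanol,FALSE,16
2-(2-butoxyethoxy)-Ethanol,FALSE,8
6-Methyl-1-octanol,FALSE,9
2-Furanmethanol,FALSE,5
Octaethylene glycol,FALSE,16
"9,12-Octadecadien-1-ol",FALSE,18
2-ethyl-1-Hexanol,FALSE,8
2-Isopropyl-5-methyl-1-heptanol,FALSE,11
"3,7-dimethyl-1,6-Octadien-3-ol",FALSE,10
3-(methylthio)-1-Propanol,FALSE,4
1-Heptadecanol,TRUE,17
1-Undecanol,TRUE,11
5-methyl-2-(1-methylethenyl)-4-Hexen-1-ol,FALSE,10
4-methyl-1-Heptanol,FALSE,8
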