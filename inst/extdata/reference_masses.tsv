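name	mass	class
glucose	180.0634	carbohydrates
fructose	180.0634	carbohydrates
sucrose	342.1162	carbohydrates
maltose	342.1162	carbohydrates
trehalose	342.1162	carbohydrates
maltotriose	504.1690	carbohydrates
raffinose	504.1690	carbohydrates
mannitol	182.0790	sugar_alcohols
glycerol	92.0473	sugar_alcohols
xylitol	152.0685	sugar_alcohols
lactic_acid	90.0317	organic_acids
acetic_acid	60.0211	organic_acids
succinic_acid	118.0266	organic_acids
citric_acid	192.0270	organic_acids
malic_acid	134.0215	organic_acids
pyruvic_acid	88.0160	organic_acids
phenyllactic_acid	166.0630	organic_acids
ethanol	46.0419	alcohols
acetoin	88.0524	ketones
diacetyl	86.0368	ketones
glycine	75.0320	amino_acids
alanine	89.0477	amino_acids
serine	105.0426	amino_acids
proline	115.0633	amino_acids
valine	117.0790	amino_acids
leucine	131.0946	amino_acids
isoleucine	131.0946	amino_acids
aspartic_acid	133.0375	amino_acids
glutamic_acid	147.0532	amino_acids
lysine	146.1055	amino_acids
arginine	174.1117	amino_acids
methionine	149.0510	amino_acids
phenylalanine	165.0790	amino_acids
tyrosine	181.0739	amino_acids
tryptophan	204.0899	amino_acids
gamma_aminobutyric_acid	103.0633	amino_acids
adenine	135.0545	nucleotides
guanine	151.0494	nucleotides
uracil	112.0273	nucleotides
hypoxanthine	136.0385	nucleotides
xanthine	152.0334	nucleotides
adenosine	267.0968	nucleotides
adenosine_monophosphate	347.0631	nucleotides
palmitic_acid	256.2402	fatty_acyls
oleic_acid	282.2559	fatty_acyls
linoleic_acid	280.2402	fatty_acyls
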