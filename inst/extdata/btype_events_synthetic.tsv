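branch_label	type	group	note
node_teleost	gain	CYP19A1	shared duplication in the zebrafish+medaka ancestor
Dare	gain	CYP8B2	zebrafish-specific duplication
Dare	gain	CYP8B3	zebrafish-specific duplication
Dare	gain	CYP17A1	zebrafish-specific duplication
Dare	gain	CYP27A1	zebrafish-specific duplication
Dare	gain	CYP46A1	zebrafish-specific duplication
Orla	gain	CYP46A1	medaka-specific duplication
Xetr	gain	CYP8B1	frog-specific duplication
Xetr	gain	CYP27A1	frog-specific duplication
Xetr	gain	CYP46A1	frog-specific duplication
Anca	gain	CYP24A1	green-anole-specific duplication
Modo	gain	CYP8B1	opossum-specific duplication
node_primates	gain	CYP11B2	duplication in the primate ancestor
node_hominoids	gain	CYP51A1-dup1	duplication in the hominoid ancestor (later CYP51P1)
node_hominoids	gain	CYP51A1-dup2	duplication in the hominoid ancestor (later CYP51P2)
Mumu	gain	CYP11B1	plausible placement (synthetic)
Rano	gain	CYP21A2	plausible placement (synthetic)
Bota	gain	CYP11B1	plausible placement (synthetic)
Tagu	gain	CYP24A1	plausible placement (synthetic)
Orla	loss	CYP7B1	medaka deletion
Orla	loss	CYP11B1	medaka deletion
Orla	loss	CYP39A1	medaka deletion
Xetr	loss	CYP11B1	frog deletion
Anca	loss	CYP11A1	green anole deletion
Anca	loss	CYP21A2	green anole deletion
Anca	loss	CYP26A1	green anole deletion
Gaga	loss	CYP27B1	chicken deletion
Tagu	loss	CYP11B1	zebra finch deletion
Tagu	loss	CYP21A2	zebra finch deletion
Tagu	loss	CYP27A1	zebra finch deletion
Modo	loss	CYP17A1	opossum deletion
Modo	loss	CYP26B1	opossum deletion
Cafa	loss	CYP11B1	plausible placement (synthetic)
Bota	loss	CYP11B2	plausible placement (synthetic)
Mamu	loss	CYP26C1	plausible placement (synthetic)
Hosa	pseudogenization	CYP21A1P	human pseudogenization of a CYP21A copy
Hosa	pseudogenization	CYP51P1	human processed pseudogene
Hosa	pseudogenization	CYP51P2	human processed pseudogene
Patr	pseudogenization	CYP51-like	plausible placement (synthetic)
Mamu	pseudogenization	CYP21A-like	plausible placement (synthetic)
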