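(((((((((Hosa:6.93050044304,Patr:6.93050044304):23.0671880418,Mamu:29.9976884848):14.4816427168,Caja:44.4793312016):48.6169434064,(Mumu:20.688061024,Rano:20.688061024):72.408213584):7.2408213584,(Bota:80.6834379936,Cafa:80.6834379936):19.6536579728):65.1673922256,Modo:165.504488192):157.229263782,((Gaga:101.371499018,Tagu:101.371499018):188.261355318,Anca:289.632854336):33.1008976384):41.376122048,Xetr:364.109874022):49.6513464576,(Orla:237.912701776,Dare:237.912701776):175.848518704);
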