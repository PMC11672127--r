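"id","reactants","products","catalysts","g_a","g_a_lower","dg","note"
"R1","CO + H2O","HCOOH","NH3",45.5,NA,-1.4,"ammonia-catalysed synthesis of formic acid from CO and water"
"R2","CO + NH3","HCONH2","H2O",49.5,NA,NA,"water-catalysed synthesis of formamide from CO and ammonia"
"R3","HCOOH + NH3","HCONH2 + H2O","H2O",36.2,NA,NA,"water-catalysed amino-for-hydroxyl substitution on formic acid; 41.8 when referenced to the preceding complex"
"R4","HCOOH + HCOOH","methanediol + CO2","",42.6,NA,NA,"two-hydrogen-transfer hydrogenation of formic acid (donor: formic acid)"
"R5","HCONH2 + HCOOH","aminomethanol + CO2","",41.7,NA,NA,"two-hydrogen-transfer hydrogenation of formamide (donor: formic acid)"
"R6","methanediol","CH2O + H2O","HCOOH",9.3,NA,NA,"formic-acid-catalysed dehydration of methanediol to formaldehyde"
"R7","aminomethanol","CH2O + NH3","HCOOH",4,NA,NA,"formic-acid-catalysed deamination of aminomethanol to formaldehyde"
"R8","CO + HCOOH","CH2O + CO2","",52,NA,NA,"two-hydrogen-transfer CO/formaldehyde interconversion (donor: formic acid)"
"R10","HCOOH + HCOOH","CH2O + H2O + CO2","",42.1,NA,NA,"two-hydrogen transfer linking water, formaldehyde and formic acid (donor: formic acid)"
"R11","HCONH2 + HCOOH","CH2O + NH3 + CO2","",36.8,NA,NA,"two-hydrogen transfer linking ammonia, formaldehyde and formamide (donor: formic acid)"
"R12","CO2 + HCOOH","HCOOH + CO2","",31.4,NA,NA,"degenerate two-hydrogen exchange between formic acid and CO2"
"R13","HCONH2 + CO2","HNCO + HCOOH","",40.7,NA,NA,"two-hydrogen-transfer dehydrogenation of formamide to isocyanic acid; acceptor assignment inferred"
"R14","CO2 + H2O","carbonic-acid","HCOOH",24.6,NA,NA,"formic-acid-catalysed hydration of CO2; endothermic product; barrier assignment from the catalysed-hydration comparison is approximate"
"R17","formaldimine + H2O","aminomethanol","HCOOH",13.3,NA,NA,"formic-acid-catalysed hydration of formaldimine (28.7 with water as the shuttle)"
"R18","HNCO","NCOH","HCOOH",3.3,NA,NA,"formic-acid-catalysed isomerisation of isocyanic to cyanic acid; endothermic product"
"R19","formaldimine + CO2","HCN + HCOOH","",29.9,NA,NA,"two-hydrogen-transfer dehydrogenation of formaldimine to hydrogen cyanide; acceptor assignment inferred"
"R21","CH3OH + HCOOH","CH4 + H2O + CO2","",67.3,NA,NA,"formic-acid-mediated conversion of methanol to methane"
"R22","aminomethanol","formaldimine + H2O","HCOOH",19.1,NA,5.8,"formic-acid-catalysed dehydration of aminomethanol to formaldimine; endothermic by 5.8"
"R25","formaldimine + CO + H2","2-aminoacetaldehyde","",49.6,44.6,NA,"coupling of formaldimine with CO and H2; barrier quoted as a range"
"R26","formaldimine + H2 + CH2O","ethanolamine","",49.6,44.6,NA,"coupling of formaldimine with H2 and formaldehyde; barrier quoted as a range"
"R27","formaldimine + formaldimine + H2","ethylenediamine","",49.6,44.6,NA,"coupling of two formaldimine molecules with H2; barrier quoted as a range"
"R28","HCN + CO + H2","aminoketene","",55,50.8,NA,"coupling of hydrogen cyanide with CO and H2; barrier quoted as a range"
"R29","HCN + H2 + CH2O","iminoethanol","",55,50.8,NA,"coupling of hydrogen cyanide with H2 and formaldehyde; barrier quoted as a range"
"R30","HCN + CO + H2O","iminoglycine","",55,50.8,NA,"coupling of hydrogen cyanide with CO and water; barrier quoted as a range"
"R31","aminoketene + HCOOH","2-aminoacetaldehyde + CO2","",33.8,27.8,NA,"two-hydrogen-transfer hydrogenation of aminoketene; group barrier range"
"R32","iminoethanol + HCOOH","ethanolamine + CO2","",33.8,27.8,NA,"two-hydrogen-transfer hydrogenation of iminoethanol; group barrier range"
"R33","2-aminoacetaldehyde + HCOOH","ethanolamine + CO2","",39.5,NA,NA,"two-hydrogen-transfer hydrogenation of 2-aminoacetaldehyde (explicit value; group quoted as 27.8-33.8)"
"R34","2-aminovinyl-alcohol + HCOOH","ethanolamine + CO2","",33.8,27.8,NA,"two-hydrogen-transfer hydrogenation of 2-aminovinyl alcohol; group barrier range; donor assignment inferred"
"R35","iminoethanol","2-aminovinyl-alcohol","",29.2,NA,NA,"isomerisation of iminoethanol to 2-aminovinyl alcohol"
"R36","aminoketene + formaldimine","2-aminoacetaldehyde + HCN","",33.8,27.8,NA,"two-hydrogen-transfer hydrogenation of aminoketene by formaldimine; group barrier range; donor assignment inferred"
"R37","ethanolamine","vinylamine + H2O","HCOOH",55.4,NA,NA,"formic-acid-catalysed dehydration of ethanolamine to vinylamine"
"R38","ethylenediamine","vinylamine + NH3","HCOOH",NA,NA,NA,"formic-acid-catalysed deamination of ethylenediamine to vinylamine; barrier not available"
"R39","vinylamine","ethanimine","CH2O",26.5,NA,NA,"isomerisation of vinylamine to ethanimine accompanying formaldehyde amination; 34.7 when referenced to the preceding complex"
"R40","formaldimine + HCOOH","glycine","HCOOH",41.9,NA,NA,"formic-acid-catalysed coupling of formaldimine and formic acid to glycine"
"R41","iminoglycine + HCOOH","glycine + CO2","",27.7,NA,NA,"two-hydrogen-transfer hydrogenation of iminoglycine to glycine"
"R42","glycine + CH2O","serine","HCOOH",47.9,NA,NA,"formic-acid-catalysed coupling of glycine and formaldehyde to serine"
"R43","iminoglycine + H2 + CH2O","serine","",47.9,NA,NA,"direct coupling of iminoglycine, H2 and formaldehyde to serine"
"R44","iminoethanol + HCOOH","serine","HCOOH",40.9,NA,NA,"formic-acid-catalysed coupling of iminoethanol and formic acid to serine"
"R45","2-aminovinyl-alcohol + CO + H2O","serine","",60,NA,NA,"direct coupling of 2-aminovinyl alcohol, CO and water to serine"
"R46","ethanimine + HCOOH","alanine","HCOOH",40.8,NA,NA,"formic-acid-catalysed coupling of ethanimine and formic acid to alanine"
"R47","vinylamine + CO + H2O","alanine","",54.1,NA,NA,"direct coupling of vinylamine, CO and water to alanine"
"R4p","HCOOH + H2","methanediol","NH3",45.5,NA,NA,"ammonia-catalysed hydrogenation of formic acid by H2 (alternative to R4)"
"R5p","HCONH2 + H2","aminomethanol","NH3",49.7,NA,NA,"ammonia-catalysed hydrogenation of formamide by H2 (alternative to R5); 69.9 uncatalysed"
"R6p","methanediol","CH2O + H2O","H2O",23.2,NA,NA,"water-catalysed dehydration of methanediol (alternative to R6)"
"R7p","CH2O + NH3","aminomethanol","NH3",21.7,NA,NA,"ammonia-catalysed amination of formaldehyde (alternative shuttle to R7's reverse)"
"R40p","formaldimine + CO + H2O","glycine","H2O",47,NA,NA,"water-catalysed four-body coupling of formaldimine, CO and water to glycine (alternative to R40)"
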