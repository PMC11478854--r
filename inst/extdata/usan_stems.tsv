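stem	position	label
guan	prefix	antihypertensive (guanidine derivatives)
cef	prefix	cephalosporin antibiotic
rifa	prefix	rifamycin antibacterial
sulfa	prefix	sulfonamide anti-infective
arte	prefix	artemisinin antimalarial
io	infix	iodine-containing contrast/agent
erg	infix	ergot alkaloid derivative
mab	suffix	monoclonal antibody
ciguat	suffix	soluble guanylate cyclase stimulator
stat	suffix	enzyme inhibitor
vastatin	suffix	HMG-CoA reductase inhibitor
olol	suffix	beta-adrenergic blocker
pril	suffix	ACE inhibitor
sartan	suffix	angiotensin II receptor antagonist
dipine	suffix	dihydropyridine calcium channel blocker
oxetine	suffix	fluoxetine-type antidepressant
azepam	suffix	benzodiazepine (diazepam type)
cillin	suffix	penicillin antibiotic
mycin	suffix	antibiotic (Streptomyces strains)
tinib	suffix	tyrosine kinase inhibitor
zomib	suffix	proteasome inhibitor
ciclib	suffix	cyclin-dependent kinase inhibitor
parib	suffix	PARP inhibitor
lukast	suffix	leukotriene receptor antagonist
prazole	suffix	proton pump inhibitor
tidine	suffix	H2 receptor antagonist
setron	suffix	serotonin 5-HT3 receptor antagonist
triptan	suffix	5-HT1 receptor agonist (antimigraine)
gliptin	suffix	dipeptidyl peptidase-4 inhibitor
gliflozin	suffix	SGLT2 inhibitor
afil	suffix	PDE5 inhibitor
asone	suffix	corticosteroid
onide	suffix	topical corticosteroid (acetal derivatives)
terol	suffix	bronchodilator (phenethylamine type)
caine	suffix	local anesthetic
arone	suffix	antiarrhythmic (benzofuran derivatives)
xaban	suffix	direct factor Xa inhibitor
gatran	suffix	direct thrombin inhibitor
parin	suffix	heparin derivative
plase	suffix	plasminogen activator
citabine	suffix	nucleoside antimetabolite
rubicin	suffix	anthracycline antineoplastic
platin	suffix	platinum antineoplastic
taxel	suffix	taxane antineoplastic
navir	suffix	HIV protease inhibitor
oxacin	suffix	fluoroquinolone antibacterial
conazole	suffix	azole antifungal
fungin	suffix	echinocandin antifungal
dronate	suffix	bisphosphonate
cizumab	suffix	humanized monoclonal antibody (nanobody type)
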