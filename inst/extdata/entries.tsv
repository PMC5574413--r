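accession	trivial_name	iupac_name	fingerprint	formula	category	source_organisms
CA00047	Neurosporene	7,8-dihydro-psi,psi-carotene	7,8+H, psi,psi	C40H58	Hydrocarbons
CA00322	beta-Cryptoxanthin	(3R)-beta,beta-caroten-3-ol	(3R), 3-OH, beta,beta	C40H56O	Hydroxycarotenoids
CA00628	alpha-Carotene epoxide	5,6-epoxy-5,6-dihydro-beta,epsilon-carotene	5,6+H, 5,6-Epoxy, beta,epsilon		Epoxycarotenoids
CA00161	Anhydrorhodovibrinal	3,4-didehydro-1,2-dihydro-1-methoxy-psi,psi-caroten-20-al	3,4-H, 1,2+H, 1-Methoxy, 20-al, psi,psi		Aldehydes
CA00184	Ketohydroxylycopene	3'-hydroxy-psi,psi-caroten-4-one	3'-OH, 4=O, psi,psi		Ketones
CA00283	Torularhodin	3',4'-didehydro-beta,psi-caroten-16'-oic acid	3',4'-H, 16'-COOH, beta,psi	C40H54O2	Carboxylic-acids
CA00288	Neurosporaxanthin		4'-COOH, 4'-apo, beta,psi	C35H46O2	Apocarotenoids
CA00572	Actinioerythrol	(3S,3'S)-3,3'-dihydroxy-2,2'-dinor-beta,beta-carotene-4,4'-dione	(3S,3'S), 3-OH, 3'-OH, 4=O, 4'=O, 2-nor, 2'-nor, beta,beta	C38H48O4	Norcarotenoids
CA00584	beta-Carotenone	5,6,5',6'-diseco-beta,beta-carotene-5,6,5',6'-tetraone	5=O, 6=O, 5'=O, 6'=O, 5,6-seco, 5',6'-seco, beta,beta		Secocarotenoids
CA00196	Retrodehydro-gamma-carotene	4',5'-didehydro-4,5'-retro-beta,psi-carotene	4',5'-H, 4,5'-retro, beta,psi	C40H54	Retrocarotenoids
CA00413	Peridininol 5,8-furanooxide		(3S,5R,6S,3'S,5'R,6'S), 6',7'-H, 5,6+H, 5',6'+H, 3-OH, 3'-OH, 5'-OH, 5,8-Epoxy, 19,11-olide, beta,beta		Olidecarotenoids
CA00341	Trollein	(3S,5R,6R,3'R)-6,7-didehydro-5,6-dihydro-beta,beta-carotene-3,5,3'-triol	(3S,5R,6R,3'R), 6,7-H, 5,6+H, 3-OH, 5-OH, 3'-OH, beta,beta		Allenecarotenoids
CA00296	Crassostreaxanthin A		(3R,3'R,5'R,6'S), 7,8-H, 1',2'+H, 5',6'+H, 7',8'+H, 3-OH, 1'=O, 8'=O, 3',6'-Epoxy, 16'-nor, beta,psi		Acetylenecarotenoids
CA00886	Crocetindial	8,8'-diapocarotene-8,8'-dial	8-al, 8'-al, 8-apo, 8'-apo	C20H24O2	Diapocarotenoids
FX0001	Fucoxanthin	(3S,5R,6S,3'S,5'R,6'R)-5,6-epoxy-3'-ethanoyloxy-3,5'-dihydroxy-6',7'-didehydro-5,6,7,8,5',6'-hexahydro-beta,beta-caroten-8-one	(3S,5R,6S,3'S,5'R,6'R), 6',7'-H, 5,6+H, 7,8+H, 5',6'+H, 3-OH, 5'-OH, 3'-Ethanoyloxy, 8=O, 5,6-Epoxy, beta,beta
FX0002	Astaxanthin	(3S,3'S)-3,3'-dihydroxy-beta,beta-carotene-4,4'-dione	(3S,3'S), 3-OH, 3'-OH, 4=O, 4'=O, beta,beta	C40H52O4
CA00309	beta-Carotene	beta,beta-carotene	beta,beta	C40H56		Cyanidioschyzon merolae;Prochlorothrix hollandica PCC 9006;Cyanophora paradoxa;Glaucocystis nostochinearum
FX0003	Zeaxanthin	(3R,3'R)-beta,beta-carotene-3,3'-diol	(3R,3'R), 3-OH, 3'-OH, beta,beta	C40H56O2		Cyanidioschyzon merolae;Prochlorothrix hollandica PCC 9006;Cyanophora paradoxa;Glaucocystis nostochinearum
FX0004	Lycopene	psi,psi-carotene	psi,psi	C40H56
FX0005	alpha-Carotene	(6'R)-beta,epsilon-carotene	(6'R), beta,epsilon	C40H56
FX0006	(13Z)-beta-Carotene	(13Z)-beta,beta-carotene	(13Z), beta,beta	C40H56
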