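name,smiles,cls,qed,MW,ALOGP,HBA,HBD,PSA,ROTB,AROM,ALERTS
aspirin,CC(=O)Oc1ccccc1C(=O)O,drug,0.5501217966938848,180.15899999999996,1.3101,4,1,63.60000000000001,2,1,2
paracetamol,CC(=O)Nc1ccc(O)cc1,drug,0.5950261967780849,151.165,1.3505999999999998,2,2,49.33,1,1,1
ibuprofen,CC(C)Cc1ccc(C(C)C(=O)O)cc1,drug,0.8215995486924976,206.28499999999997,3.073200000000001,2,1,37.3,4,1,0
naproxen,COc1ccc2cc(C(C)C(=O)O)ccc2c1,drug,0.8810778082204156,230.26299999999998,3.036500000000001,3,1,46.53,3,2,0
caffeine,Cn1cnc2c1c(=O)n(C)c(=O)n2C,drug,0.5384628262372215,194.194,-1.0293,3,0,61.82,0,2,0
diazepam,CN1c2ccc(Cl)cc2C(=Nc3ccccc3)CC1=O,drug,0.7832351299904947,284.74600000000004,3.827300000000002,1,0,32.67,1,2,0
lidocaine,CCN(CC)CC(=O)Nc1c(C)cccc1C,drug,0.8489671904749567,234.343,2.5837400000000006,2,1,32.34,5,1,0
procaine,CCN(CC)CCOC(=O)c1ccc(N)cc1,drug,0.6038456847188672,236.315,1.7673999999999999,4,1,55.56,6,1,2
atenolol,CC(C)NCC(O)COc1ccc(CC(N)=O)cc1,drug,0.637673978167625,266.34099999999995,0.45210000000000006,4,3,84.57999999999998,8,1,0
propranolol,CC(C)NCC(O)COc1cccc2ccccc12,drug,0.8375057924076362,259.34900000000005,2.5775000000000006,3,2,41.489999999999995,6,2,0
metoprolol,COCCc1ccc(OCC(O)CNC(C)C)cc1,drug,0.7135696186852986,267.36899999999997,1.6132,4,2,50.72,9,1,0
warfarin,CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O,drug,0.7476258148419598,308.3330000000001,3.609600000000003,4,1,67.50999999999999,4,3,1
phenytoin,O=C1NC(=O)C(c2ccccc2)(c2ccccc2)N1,drug,0.8001945345367882,252.27300000000002,1.7696,2,2,58.2,2,2,1
carbamazepine,NC(=O)N1c2ccccc2C=Cc2ccccc21,drug,0.748363450121821,236.274,3.3872000000000018,1,1,46.330000000000005,0,2,0
chlorpromazine,CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21,drug,0.7918053413291345,318.8730000000001,4.894400000000004,3,0,6.48,4,2,0
haloperidol,OC1(c2ccc(Cl)cc2)CCN(CCCC(=O)c2ccc(F)cc2)CC1,drug,0.7593452850579151,375.87100000000004,4.425600000000004,3,1,40.54,6,2,1
diphenhydramine,CN(C)CCOC(c1ccccc1)c1ccccc1,drug,0.7845504400951161,255.36100000000002,3.3542000000000023,2,0,12.47,6,2,0
cimetidine,CC1=C(CSCCNC(=NC)NC#N)N=CN1,drug,0.2346588097545297,252.34700000000004,0.5973999999999997,5,3,88.88999999999999,5,1,5
sulfamethoxazole,Cc1cc(NS(=O)(=O)c2ccc(N)cc2)no1,drug,0.804736706639606,253.28300000000002,1.3660199999999998,5,2,98.22,3,2,1
amoxicillin,CC1(C)SC2C(NC(=O)C(N)c3ccc(O)cc3)C(=O)N2C1C(=O)O,drug,0.5530315284690744,365.4110000000001,0.023700000000000443,7,4,132.96,4,1,1
ethanol,CCO,nondrug,0.40680796565539457,46.069,-0.0014000000000000123,1,1,20.23,0,0,0
acetone,CC(C)=O,nondrug,0.3982369618339747,58.080000000000005,0.5952999999999999,1,0,17.07,0,0,0
toluene,Cc1ccccc1,nondrug,0.45880627965754545,92.14099999999999,1.99502,0,0,0.0,0,1,0
hexane,CCCCCC,nondrug,0.4629542813199688,86.178,2.5866000000000007,0,0,0.0,3,0,1
dmso,CS(C)=O,nondrug,0.3981850774633207,78.136,-0.005299999999999971,1,0,17.07,0,0,0
thf,C1CCOC1,nondrug,0.410937601049349,72.107,0.7968,1,0,9.23,0,0,0
ethyl_acetate,CCOC(C)=O,nondrug,0.43785087777866244,88.106,0.5694,2,0,26.3,1,0,1
acetonitrile,CC#N,nondrug,0.3869805798690774,41.053,0.52988,1,0,23.79,0,0,0
pyridine,c1ccncc1,nondrug,0.4531479654842905,79.10199999999998,1.0816,1,0,12.89,0,1,0
aniline,Nc1ccccc1,nondrug,0.48007546344555985,93.12899999999999,1.2688000000000001,1,1,26.02,0,1,1
phenol,Oc1ccccc1,nondrug,0.514729544768675,94.11299999999999,1.3921999999999999,1,1,20.23,0,1,0
benzaldehyde,O=Cc1ccccc1,nondrug,0.4956362681365689,106.12399999999997,1.4990999999999999,1,0,17.07,1,1,1
benzoic_acid,O=C(O)c1ccccc1,nondrug,0.6106035394285075,122.12299999999996,1.3848,2,1,37.3,1,1,0
cyclohexane,C1CCCCC1,nondrug,0.42231618686094674,84.162,2.3406000000000002,0,0,0.0,0,0,0
octanol,CCCCCCCCO,nondrug,0.5470483699238978,130.23100000000002,2.3392000000000013,1,1,20.23,6,0,1
glycerol,OCC(O)CO,nondrug,0.3814944322102413,92.09400000000001,-1.6681000000000001,3,3,60.69,2,0,0
urea,NC(N)=O,nondrug,0.3705073514035382,60.056,-0.9762000000000002,1,2,69.11,0,0,0
triethylamine,CCN(CC)CC,nondrug,0.5183748699715436,101.193,1.3481,1,0,3.24,3,0,0
diethyl_ether,CCOCC,nondrug,0.4752681489358652,74.123,1.0428000000000002,1,0,9.23,2,0,0
triacontane,CCCCCCCCCCCCCCCCCCCCCCCCCCCCCC,nondrug,0.11538186127227373,422.82600000000036,11.948999999999982,0,0,0.0,27,0,1
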