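"id","g0_tumor","g0_oar","geval_tumor","geval_oar","d_eval","clinical_d_adapt","TC","NTC","age","sex","ecog_ps","biomarker_a","biomarker_b","biomarker_c","snp_a","snp_b","snp_c","mirna_a","mirna_b"
"P0001",0,0,36.0997928809375,15.4723067772575,2,3.4,0,1,72.3518189728657,0,0,-1.5397961226351,-2.40161776050478,0.638305109056757,1,0,2,-0.863917684958232,-0.184340038877873
"P0002",0,0,35.323631465435,13.314423205331,2,3,1,0,71.2570904058485,1,1,0.400282565425409,0.0392400027331692,0.597833526210671,0,0,0,0.176714842266577,0.130579214766329
"P0003",0,0,36.5773444529623,15.7448686454445,2,2.9,0,0,65.5965198669215,0,2,1.18736361389995,-0.689739362450777,0.911356036587575,1,1,1,-1.19806939206359,-0.200204721999655
"P0004",0,0,38.0810016524047,18.3142022839747,2,1.6,0,0,49.085186433093,1,0,2.19980011412988,-0.0280021587806661,1.9850578861261,0,1,0,1.42126360162647,1.24815175486534
"P0005",0,0,41.391747770831,15.900789336767,2,1.5,0,0,69.9586059831577,1,1,0.0318350308455349,0.743273208882405,0.397378593565167,2,0,0,-0.0828447941606,0.634216756381047
"P0006",0,0,38.0876775868237,18.8962784879841,2,1.7,0,0,64.550970083768,0,1,0.366631658886453,-0.188792299514343,0.86321697874057,2,0,0,0.281530003000559,-1.65443620305366
"P0007",0,0,36.0609700866044,18.894134124741,2,3.8,1,0,63.7536359463574,1,2,-0.742189128160461,1.80495862889104,1.46836211408205,0,1,0,0.800369255685512,0.0152555521910794
"P0008",0,0,34.3716870956123,17.5490062315948,2,2.3,0,1,53.2339809288058,1,0,-1.10009347302394,-1.46555486156289,0.809856389652194,0,1,0,1.11624972413859,0.119203810629755
"P0009",0,0,37.3428500667214,16.2962440778501,2,2,0,0,61.174799559131,1,1,-1.38658028763755,-0.153253338211898,1.03169228535789,1,1,1,0.69216022769692,0.271306254207554
"P0010",0,0,40.8320120181888,16.527200628072,2,3.1,1,1,68.3435324815976,1,1,-0.758886146325571,-2.17261167036215,0.90540268385585,0,1,1,0.665859528894677,-1.17687204109755
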