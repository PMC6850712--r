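V1,V2,V3,group
1.6636144198612142,0.5293843927927433,0.11975301102315827,g1
0.49731173392270167,1.7356630419591874,1.0139421083925908,g1
0.97131842629795806,0.56490615986792792,0.4826923899720611,g1
1.2256035000151673,1.2545956025882989,-0.049597249386029454,g1
1.543913239215277,1.5571318060787118,0.4535580402476147,g1
1.1381822859824002,0.62309476566095434,0.13153240957014453,g1
0.21735874173405401,0.78512843076495109,-0.56033532499959449,g1
2.3271655008471046,-1.168014837778387,-0.48635243512039827,g1
0.70966350902376085,0.34395191695180161,-0.27892263703822517,g1
1.0609243532700616,1.6686686131267479,-0.16646120821877278,g1
3.284865438484009,1.8114484377428153,0.1332659024287674,g1
0.076459961761416118,-0.25565266971098588,-0.17140234100020901,g1
2.3999278236308776,0.6919300671108104,-0.13061807854906862,g1
1.0661567259537856,-0.55110435636827459,0.62063819198123338,g1
0.080578960558630452,1.0859726967980066,0.21064746518124122,g1
1.5276316078464198,2.4953658401824419,-0.65050455491529835,g2
1.2352613506450878,0.55324363884994965,-1.9247107678406348,g2
0.38015120595571988,0.71397568072879669,-1.7209961676188668,g2
1.3313648982944848,2.1857733000667938,-0.98143424852395356,g2
-0.24473012235121461,0.51190551292299913,-2.0740657066767678,g2
0.033864628515487827,1.7136650866774605,0.33032776705376055,g2
1.7726445926387384,2.3350160662839801,0.21246729525082997,g2
1.6569850785148263,0.26560614873078547,-2.1818259993770397,g2
0.85198340615828272,0.23139528072674587,-0.19041298307827947,g2
2.1875056921605873,1.5878939961566387,0.013184209889376186,g2
0.32848213923929859,1.0545080703228153,-1.3426931402011055,g2
-0.30908540181598398,-0.80082272677866673,-3.1765357348258254,g2
1.4758811690407836,1.4330353375779166,0.73491003402514088,g2
0.76027603670185173,1.2173174447489912,-1.4403626960100997,g2
0.91898820766454592,1.3261029267923412,-0.66172434280702608,g2
2.0142301212271474,0.58535134050174686,0.67507460726540924,g3
1.4432459889819447,0.42545076107590041,0.52382164171547929,g3
2.6979652466224744,-0.18039478530312805,0.68084693908408833,g3
1.6697085130916989,0.25856930633144115,-1.5448349171266405,g3
3.4270581748783453,1.1737787340183081,0.91331215240445385,g3
1.3911214995615901,-1.3179070285189876,-0.33139847914589465,g3
3.14392344549006,1.2925687694195134,-0.092682012327001129,g3
2.7087826261400423,0.73510671782439874,0.46042675362717711,g3
2.741427071188693,-0.61482537795040426,-1.7244748797731115,g3
2.8888313913999708,-0.14252902187873559,-1.040818730457308,g3
3.3262437483187459,0.65153616546406157,0.048502644167249476,g3
3.5849958228502916,0.046145087966020043,-0.17175630945729498,g3
3.6314480843641874,0.76554049127283497,-0.64118881820179419,g3
3.2698896944466695,0.17760038421357829,-1.0228668055902297,g3
0.93464875572718364,0.20674447305855281,-1.9452715045641367,g3
-1.3496497453744902,-0.38276514475448631,1.6375843712547282,g4
-1.8877479381327136,-0.056390144227014494,2.6887725731462124,g4
-2.3983467276221226,-0.48830060674730325,1.2487808497650299,g4
-1.610690973683329,0.4893710156192429,2.056613087627658,g4
-1.3739244277968763,-1.2672895416975289,0.13695086595838557,g4
-1.511296054330272,-1.0723976695815784,1.0899415809795789,g4
-2.0997381761074227,-0.77006721577412729,2.2140072156369723,g4
-1.3474788813062033,1.415918105949904,1.4227861888463604,g4
-3.031376369933211,-1.1201293132015908,1.1180503500818759,g4
0.060442167040460459,-1.144745095983605,1.8987722453547868,g4
-1.3592634337123632,0.82724327969825884,1.0648336537708387,g4
-1.363034353435443,-0.056905125674367896,1.9793042820715949,g4
0.079718263813536305,0.57641930739892444,1.5744587978820279,g4
-2.0088922169687566,-1.6478441775200445,1.9603096993822691,g4
-1.1195282219957901,-1.2635029038120167,1.5992699460919506,g4
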