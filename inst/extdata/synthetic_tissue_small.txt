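cell_id x y
1 69.48103352025139 7.58981192764968
1 68.32360891365221 9.27017859740936
1 67.12499729811277 10.94706867792955
1 65.40300549708665 11.92886676427239
1 63.75878248416813 10.79981419816453
1 62.31829034721918 9.33574172769221
1 61.18840631779752 7.67144713018491
1 62.01611977037830 5.84891675458308
1 63.40274306436383 4.31289095363927
1 65.23744014789469 3.50809063158204
1 66.97284732546746 4.55464583399784
1 68.62165569916380 5.79782800112405
2 35.73279483758957 8.96000747839638
2 34.83816625939498 10.75406994113814
2 33.29666736904507 12.11585409656659
2 31.46132001337920 12.91010712368015
2 29.62806432372887 12.04985543071895
2 28.04470226128648 10.74324256414983
2 27.37498162817554 8.89216265609171
2 28.59110383119247 7.27870943687348
2 29.94455768472232 5.74418624449459
2 31.62544583163244 4.69314437593810
2 33.36599846460652 5.67367112070419
2 34.73252840814804 7.20769711448892
3 34.82091637791704 36.83416780302652
3 34.01996199871949 38.72625255431546
3 32.75815906794488 40.34839358344382
3 30.92571512438091 41.20548311783762
3 29.06442012856528 40.44706310320524
3 28.09269222023264 38.65613915959539
3 27.46755153790017 36.68877687845133
3 27.42219680895085 34.66000640354590
3 28.77205691070704 33.17094695821579
3 30.79845713816546 33.00679287841520
3 32.76629194270721 33.61384298661269
3 34.39058788541726 34.85449617927885
4 59.67184666652511 23.72666320623992
4 58.56250442117184 25.34036120680974
4 57.16738563036963 26.74073089291356
4 55.72302005370699 28.07718324522878
4 53.80068828746912 28.25602848409066
4 52.13529660869205 27.24648696189263
4 50.98588031172255 25.65506007052212
4 50.63680879197554 23.74206916163670
4 51.23017779674154 21.87377823945397
4 52.38374196496046 20.28009922534186
4 54.10787280260965 19.41879148873482
4 56.02812480312234 19.73346932760865
4 57.81287265188290 20.58740828653088
4 59.30063721867469 21.84217794255258
5 50.63734303488295 6.61638255463073
5 49.77319926425067 8.36700337075799
5 48.00250599549319 9.29753125634048
5 46.14699938978097 10.04404329075141
5 44.24160958873095 9.62379990186964
5 43.51267796551508 7.81276718207123
5 43.85170412646472 5.84065462379901
5 44.55315529872595 3.96736923922065
5 46.26564522156046 3.02616857697696
5 48.15326327124541 3.64193003607227
5 49.75363139916760 4.85320391386488
6 94.52348230137007 21.25856495312387
6 94.80640453201042 23.17294023262473
6 93.81774828608705 24.76343509083119
6 91.99385705814113 25.35061437214620
6 90.04106811740472 25.26518401484696
6 88.20148377289821 24.67674820676619
6 86.95900801259783 23.20569999267667
6 86.30566575895406 21.36649028232324
6 86.28149981057346 19.44239626382316
6 87.38730340114518 17.88211982016601
6 89.20977790359416 17.19686580928789
6 91.15284893815422 17.00543442821311
6 92.92499553621685 17.73300805402780
6 93.86370096106381 19.41689875112914
7 19.04701842510988 8.85596389784895
7 18.87157869720075 10.71983819926573
7 17.36912343004149 11.82605215978297
7 15.49967000699575 12.33667180355661
7 13.70109452209250 13.02925709438028
7 11.89881723785695 12.54600513059169
7 11.02185480213917 10.83142615692311
7 10.36234846362762 9.00433234661709
7 10.28296256850279 7.10977431080506
7 11.51271119092107 5.71102873826498
7 13.34339827659211 5.07964188442855
7 15.24795256762555 4.78885545460527
7 16.95240436928999 5.59314528512364
7 18.06430549021086 7.18328649732100
8 67.22178239137409 36.98873100909016
8 67.03373341300181 39.02287399043226
8 65.45946073586794 40.34143034761050
8 63.40612399609770 40.61718160741692
8 61.50636683192470 39.85258378447898
8 60.56821702409675 38.04684250699613
8 60.63258215426605 35.96839998403689
8 61.31842361671037 34.02063566979487
8 63.01679527698084 32.96539598028504
8 64.93000857638548 33.54529548634140
8 66.23883263631491 35.15239741778580
9 25.52098682395259 23.49560501525619
9 25.21882056127541 25.43527067384970
9 23.76038586252712 26.69466105165826
9 21.82387035498616 27.03176355871432
9 19.93110506460510 26.58179791081462
9 18.70121569879750 25.07408040347477
9 18.02513564362731 23.22375475516451
9 18.43900840193813 21.38639495375011
9 20.12972954203648 20.52399035024566
9 22.08170644115073 20.24120508570134
9 24.00490848304311 20.17139324397173
9 25.31346689935165 21.53430209127248
10 16.82882320701773 37.17181831092520
10 16.93759036885928 39.10901397316124
10 15.76428620769883 40.62389479268842
10 13.94336774823651 41.29243790435700
10 12.02207994630959 41.11217504923859
10 10.53144321105659 39.90422915712357
10 9.70131710730344 38.13248451705737
10 9.42473226179851 36.21251165274138
10 10.24076925753191 34.48351773573302
10 11.82246231632297 33.34246665701556
10 13.68819391023835 32.81673814446569
10 15.45984977364733 33.53337775034554
10 16.29056426121085 35.28386888268928
11 53.01565762133038 38.23786833650958
11 52.67151639370390 40.08341316356128
11 51.15819447719332 41.25076863991755
11 49.40930464692759 42.10279667429212
11 47.52478932816084 42.35774748028655
11 45.83453970517364 41.47148963515288
11 44.56935775161156 40.00783269375140
11 44.06670010939560 38.17288759415581
11 45.03300989926695 36.53055544523202
11 46.49045965213315 35.24880655913566
11 47.83418097605247 33.85508237050257
11 49.65324651944870 33.62749068726229
11 51.04606677719462 34.89533137768220
11 51.98731803726064 36.59475009764031
12 85.99600694994996 38.04799658068717
12 86.12445711549391 39.97889987993268
12 84.84753481326958 41.41118393416583
12 83.00720384223057 42.13869670425964
12 81.06452922407301 42.49119366919473
12 79.25638919690435 41.81404642691630
12 77.89228498991460 40.37605482807898
12 76.60478811943912 38.86875636794690
12 76.20451132571519 37.00318618603579
12 77.30002032059741 35.43939488759300
12 79.11021060379552 34.62825860207776
12 80.80213597349154 33.59417868360892
12 82.70476116894945 33.24934944631951
12 84.12818215205644 34.56265780215606
12 84.90601921905147 36.38746209429407
13 86.19275150840006 7.82216433079892
13 85.55272028504295 9.71380557019098
13 84.24651423733592 11.19544252511241
13 82.36779033621855 11.85784605020529
13 80.39243137972232 12.11234545441998
13 78.59450904078886 11.35699312416001
13 78.01992897295263 9.49843661242474
13 78.07521658115230 7.50492758047558
13 77.89813354161619 5.52082885910040
13 78.91482737006262 3.93504798683082
13 80.83155562499363 3.74161281919192
13 82.76846035669381 4.21682552278664
13 84.72834228130436 4.51912258642528
13 86.11301839818920 5.84859832264390
14 43.90412674189376 21.41178431487930
14 42.94138318702531 23.18666777636316
14 41.56187636856171 24.64692863728748
14 39.63935070844492 25.18353582666742
14 37.62019810190677 25.10884662027787
14 35.85051557122045 24.26649621263411
14 35.31034832039376 22.39812335745849
14 36.06720149328586 20.52485338999347
14 36.69986878733352 18.60759980368722
14 38.16178600152712 17.34784856518608
14 40.12710702520869 17.68406898590128
14 42.04252455857498 18.33431973885114
14 43.65587643506129 19.46141088059773
15 77.31926639013334 23.61169684504100
15 77.21445960960514 25.64462623368534
15 76.18958984822849 27.36947677137463
15 74.34616516449397 28.19353836192982
15 72.33934441294856 27.93837854252873
15 70.76530611658691 26.66180728529340
15 69.52308212402272 25.03785449797444
15 68.56738045705107 23.25963403564180
15 68.86260183867920 21.31963531750774
15 70.57561992828649 20.28267341207665
15 72.58044541810651 19.90165019809601
15 74.51238631767880 19.26212339567678
15 76.43947048213890 19.74504406568908
15 77.27269993063001 21.57065589018242
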