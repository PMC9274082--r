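cpg_id,coefficient
(Intercept),265.303717
cg25185396,2.4957
cg27244641,-2.030449
cg22685254,-4.880974
cg20276335,-2.677458
cg21194483,-2.198097
cg21884793,2.369281
cg23159854,-2.092082
cg21524479,-2.567469
cg26581104,-3.751357
cg23966684,-2.115354
cg20632373,-2.007783
cg26077411,-4.690107
cg21438396,2.854333
cg27190227,-4.408816
cg26609840,3.116108
cg26570590,4.609507
cg25656711,-4.338941
cg20691340,-4.477506
cg24131488,-3.235395
cg29589617,3.653955
cg20057563,3.518364
cg20654173,2.613903
cg25136461,3.546665
cg21502061,2.348907
cg25327746,-4.891006
cg21902097,-4.236467
cg21105296,-4.755303
cg28265802,2.440501
cg22833588,4.457715
cg22374120,2.379215
cg24070931,-2.122605
cg24237743,-3.124224
cg27509850,3.626423
cg29074395,2.465227
cg28447324,4.599871
cg21136350,2.489209
cg25426295,3.62779
cg28509223,4.119116
cg23994680,2.578155
cg23418877,3.624234
cg24875337,4.700806
cg28321639,-3.065332
cg24133890,-4.13269
cg28876829,-2.095149
cg21534637,-3.603969
cg25032493,2.971837
cg21610541,2.997158
cg23452017,4.585314
cg24271716,-2.624734
cg23587561,4.966696
cg29961625,2.637141
cg21638113,2.934967
cg21245169,4.207955
cg22177156,-4.451235
cg20245146,4.575221
cg24895299,4.336798
cg21750154,3.215066
cg26784147,-4.513549
cg24001455,-3.255574
cg26918823,-2.079081
cg20039448,-3.497081
cg23980589,2.18098
cg24903161,-3.048579
cg29090850,2.573591
cg20676443,-3.811376
cg21129457,2.477388
cg29281451,4.398684
cg26565385,4.084844
cg22847732,-2.122436
cg29015765,4.35107
cg23251147,-3.137865
cg25469367,-4.047537
cg29462711,-2.680118
cg24432839,-3.077835
cg20344718,-4.579992
cg26921265,-4.184589
cg25553857,-2.559127
cg20609466,-2.185111
cg25956366,4.705633
cg28182391,2.738104
cg27232520,-3.640363
cg21611348,2.390772
cg23986712,4.271506
cg28388886,2.638568
cg20678958,2.231583
cg24162930,2.275599
cg24820284,-4.410591
cg21360171,4.985464
cg25956019,-4.243426
cg23853693,-3.690604
cg20561718,3.95024
cg23793455,-2.47793
cg27012705,4.654079
cg28018749,-4.16668
cg25972713,4.704609
cg23467486,3.500657
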