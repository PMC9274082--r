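cpg_id,coefficient
(Intercept),29.573763
cg11937193,1.394832
cg12403298,1.455841
cg14399982,1.299712
cg10893680,-1.008982
cg14012082,-1.418553
cg19011692,-0.674183
cg12344309,1.435918
cg11115822,-1.483311
cg19295455,-0.990803
cg11747024,-0.946512
cg13974401,0.8903
cg15294778,1.157843
cg17168940,-0.839792
cg19794790,1.202717
cg17936930,-0.588176
cg10893444,0.56999
cg14420816,-1.454792
cg12472091,-1.439153
cg16672515,0.851036
cg11496425,0.997988
cg18765785,-1.197473
cg13939168,0.768357
cg12678924,1.220365
cg15366541,0.644997
cg15870848,-0.668114
cg17144121,0.945174
cg10578025,-1.470998
cg16141102,0.805676
cg10940784,1.488008
cg14780422,-0.897363
cg15360273,0.642959
cg18446999,-0.968457
cg16166926,-0.620561
cg12722370,-0.57569
cg11258357,-0.819061
cg16595024,-0.836638
cg19617025,1.414823
cg18297005,0.742778
cg13659112,-0.794562
cg13087657,-1.128996
cg16458935,0.561643
cg13280678,0.77445
cg15569012,-1.258594
cg13044452,-0.573054
cg12352331,-0.872135
cg14634765,1.020403
cg18231216,-1.121992
cg10211363,-0.728355
cg13641164,-1.24108
cg18334029,-1.497455
cg19010213,1.458577
cg14076804,0.797562
cg15452833,0.879238
cg18823636,1.497631
cg18201736,1.349939
cg11973004,1.38682
cg17366464,0.690561
cg10834274,-0.960103
cg17793730,0.801162
cg17671181,1.482108
cg18782461,-1.019691
cg10136492,1.169684
cg18713519,-0.784849
cg13726123,-0.941689
cg12273534,0.741771
cg13474035,0.797298
cg13062828,0.91843
cg11797191,-0.568912
cg10287798,1.228746
cg15309142,0.88753
cg18048844,0.694461
cg18557672,-0.804672
cg11648870,1.299691
cg12851924,0.664143
cg16405456,1.150629
cg10750211,-1.283881
cg14284927,0.939752
cg11191030,1.190653
cg16788282,1.44872
cg18758098,1.116038
cg18419502,1.339008
cg11024065,1.272811
cg13674512,1.112191
cg14009667,-1.156593
cg18992463,1.441902
cg11854733,1.498631
cg16468944,1.032765
cg19634015,0.915122
cg10319920,0.784763
cg13880409,0.865692
cg13666460,-0.755483
cg11887931,0.597099
cg15532741,-0.875658
cg14205092,0.516379
cg19623000,0.928602
cg13548873,-1.215516
cg18521416,-0.924116
cg12059656,-1.241367
cg12348508,-0.726834
cg13863776,-1.26589
cg12976401,0.514993
cg13458582,0.871509
cg13391431,-1.263128
cg18481633,-1.445586
cg12860173,-1.424294
cg19048349,1.289438
cg10119851,1.423295
cg17539052,1.068309
cg16627703,0.9947
cg18100489,0.821596
cg17659662,0.705081
cg11230202,0.60522
cg17715133,-0.952043
cg16711133,-1.490609
cg10523565,1.052153
cg10716400,-1.124014
cg15172899,0.842695
cg16684882,1.297621
cg16295336,-1.491277
cg19816203,1.033714
cg14710667,1.235174
cg12512120,1.187068
cg17246282,-0.758529
cg10665830,-0.543466
cg19403351,-0.842512
cg18271573,1.296009
cg18988926,-0.99943
cg12910196,0.622926
cg17063489,0.53998
cg17169128,-1.173113
cg16664585,-0.631155
cg14923835,-1.106838
cg13344113,-1.413908
cg10064489,1.060137
cg16433605,-0.521888
cg16232975,1.313954
cg14145059,0.91583
cg19334025,-0.900861
cg16852592,0.556819
cg17127776,-1.121229
cg17197024,0.996468
cg15590694,-0.956826
cg15902137,0.542812
cg19714975,-1.443341
cg15598950,0.892306
cg14282323,0.594881
cg14066598,1.259247
cg14202949,-1.41924
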