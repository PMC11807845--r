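id_exposure	method	or
GCST90302687	ivw	0.869358
GCST90302687	egger	0.848305
GCST90302687	simple_mode	0.966649
GCST90302687	weighted_median	0.939446
GCST90302687	weighted_mode	0.974522
GCST90302729	ivw	0.840213
GCST90302729	egger	0.755415
GCST90302729	simple_mode	0.755179
GCST90302729	weighted_median	0.817282
GCST90302729	weighted_mode	0.795679
GCST90302738	ivw	0.861662
GCST90302738	egger	0.960882
GCST90302738	simple_mode	0.951147
GCST90302738	weighted_median	0.916167
GCST90302738	weighted_mode	0.9735
GCST90302764	ivw	1.123457
GCST90302764	egger	0.949611
GCST90302764	simple_mode	1.034236
GCST90302764	weighted_median	1.065026
GCST90302764	weighted_mode	1.002549
GCST90302791	ivw	0.821641
GCST90302791	egger	0.904599
GCST90302791	simple_mode	0.830695
GCST90302791	weighted_median	0.835766
GCST90302791	weighted_mode	0.83982
GCST90302799	ivw	0.884779
GCST90302799	egger	0.831426
GCST90302799	simple_mode	0.950721
GCST90302799	weighted_median	0.929536
GCST90302799	weighted_mode	0.939676
GCST90302809	ivw	1.146269
GCST90302809	egger	0.806234
GCST90302809	simple_mode	1.153282
GCST90302809	weighted_median	1.097739
GCST90302809	weighted_mode	1.111253
GCST90302816	ivw	0.905374
GCST90302816	egger	0.74247
GCST90302816	simple_mode	0.842938
GCST90302816	weighted_median	0.886502
GCST90302816	weighted_mode	0.856872
GCST90302822	ivw	0.790206
GCST90302822	egger	0.714695
GCST90302822	simple_mode	0.821285
GCST90302822	weighted_median	0.812288
GCST90302822	weighted_mode	0.824288
GCST90302823	ivw	1.244661
GCST90302823	egger	1.14786
GCST90302823	simple_mode	1.297774
GCST90302823	weighted_median	1.245514
GCST90302823	weighted_mode	1.2727
GCST90302827	ivw	1.114327
GCST90302827	egger	1.305339
GCST90302827	simple_mode	1.100701
GCST90302827	weighted_median	1.137259
GCST90302827	weighted_mode	1.096709
GCST90302831	ivw	0.890241
GCST90302831	egger	0.845693
GCST90302831	simple_mode	0.987509
GCST90302831	weighted_median	0.853532
GCST90302831	weighted_mode	0.817801
GCST90302837	ivw	0.82873
GCST90302837	egger	1.197847
GCST90302837	simple_mode	0.94668
GCST90302837	weighted_median	0.868581
GCST90302837	weighted_mode	0.957628
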