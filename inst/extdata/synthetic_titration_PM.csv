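# titrant_kind: IP6
# protein_conc_uM: 1
# total_lipid_uM: 125
# composition_label: PM
titrant_conc_uM,fluorescence
0,1.005843479
1,0.9715778391
1.733588873,0.9532546519
3.005330381,0.9853125871
5.21000731,0.9682009533
9.032010701,0.9969952825
15.65779325,0.9444017296
27.14417617,0.9571768846
47.05684177,0.9042621617
81.57721731,0.9090578812
141.4213562,0.8350742749
245.1664896,0.6998864644
425.0178985,0.5834016234
736.8062997,0.4349071885
1277.319203,0.3464392826
2214.346358,0.2198095928
3838.766207,0.1260480982
6654.842384,0.09131951591
11536.76071,0.01539409154
20000,0.008406836474
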