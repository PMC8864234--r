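rank,family,canonical_name,sum_ui,uv_printed,fc,rfc_printed
1,Acanthaceae,Justicia procumbens,74,0.93,72,0.90
2,Leguminosae,Glycine tomentella,36,0.45,33,0.41
3,Commelinaceae,Tradescantia spathacea,33,0.41,20,0.25
4,Solanaceae,Lycium chinense,32,0.40,18,0.23
5,Moraceae,Morus alba,27,0.34,20,0.25
6,Crassulaceae,Graptopetalum paraguayense,26,0.33,20,0.25
7,Poaceae,Imperata cylindrica,24,0.30,20,0.25
8,Lamiaceae,Plectranthus amboinicus,22,0.28,20,0.25
9,Plantaginaceae,Plantago asiatica,21,0.26,16,0.20
10,Verbenaceae,Phyla nodiflora,18,0.22,13,0.16
11,Euphorbiaceae,Jatropha curcas,16,0.20,13,0.16
12,Lamiaceae,Mentha spicata,12,0.15,9,0.11
13,Leguminosae,Senna tora,12,0.15,9,0.11
14,Cucurbitaceae,Momordica charantia,12,0.15,8,0.10
15,Compositae,Bidens pilosa,12,0.15,7,0.09
16,Compositae,Cirsium japonicum,12,0.15,7,0.09
17,Compositae,Bidens bipinnata,10,0.13,6,0.08
18,Amaryllidaceae,Crinum asiaticum,8,0.10,8,0.10
19,Basellaceae,Anredera cordifolia,8,0.10,8,0.10
20,Compositae,Chrysanthemum morifolium,8,0.10,6,0.08
21,Compositae,Crossostephium chinense,8,0.10,6,0.08
22,Dioscoreaceae,Dioscorea alata,8,0.10,6,0.08
23,Lamiaceae,Ocimum basilicum,8,0.10,6,0.08
24,Leguminosae,Senna occidentalis,8,0.10,6,0.08
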