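element	mass
H	1.0078250319
He	4.0026032497
Li	7.0160034366
Be	9.0121831
B	11.0093054
C	12.0
N	14.0030740052
O	15.9949146221
F	18.9984031627
Ne	19.9924401762
Na	22.9897692820
Mg	23.9850417
Al	26.9815385
Si	27.9769265347
P	30.97376151
S	31.97207069
Cl	34.96885271
Ar	39.9623831237
K	38.9637064864
Ca	39.9625909
Ti	47.9479463
V	50.9439570
Cr	51.9405062
Mn	54.9380439
Fe	55.9349375
Co	58.9331950
Ni	57.9353429
Cu	62.9295977
Zn	63.9291420
Ga	68.9255735
Ge	73.9211778
As	74.9215946
Se	79.9165218
Br	78.9183376
Kr	83.9114977
Rb	84.9117897
Sr	87.9056125
Mo	97.9054048
Ag	106.9050916
Cd	113.9033585
Sn	119.9022016
Sb	120.9038120
Te	129.9062227
I	126.9044719
Xe	131.9041535
Cs	132.9054520
Ba	137.9052472
W	183.9509309
Pt	194.9647917
Au	196.9665687
Hg	201.9706434
Tl	204.9744278
Pb	207.9766525
Bi	208.9803991
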