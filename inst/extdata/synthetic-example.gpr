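ATF	1.0
4	6
"Type=GenePix Results 3"
"Wavelengths=532"
"Note=synthetic example for format documentation; not instrument data"
"PixelSize=10"
"Block"	"Row"	"Column"	"Name"	"F532 Median"	"B532 Median"
1	1	1	"VSIG4"	5230	412
1	1	2	"OPN"	11840	398
1	1	3	"VCAM1"	8455	405
1	1	4	"ALCAM"	6912	401
1	1	5	"TNFRSF1B"	9320	409
1	2	1	"BSA-biotin"	21350	420
1	2	2	"PBS"	431	415
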