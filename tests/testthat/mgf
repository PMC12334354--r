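BEGIN IONS
TITLE=/tmp/Rtmpneusco/massql-batch-fixture/synthetic_01.mzML scan=13
PEPMASS=538.514407957
CHARGE=1+
RTINSECONDS=515.733551234
SCANS=13
98.9841720494 69561.3212131
109.799337842 37733.0546334
221.812602153 6843.94822935
222.212691448 1986.34451492
236.703083168 12492.2012984
245.45349915 1266.15072114
264.603293741 22667.792415
282.888921035 45216.5811698
287.127060905 35928.9053621
301.31760145 45180.1862686
428.437618812 79047.066999
436.457095659 1618.44159307
440.269933467 86951.6515164
468.373132138 8855.08518513
527.689702034 37899.2966762
537.665331717 1452.05179463
END IONS

BEGIN IONS
TITLE=/tmp/Rtmpneusco/massql-batch-fixture/synthetic_01.mzML scan=32
PEPMASS=594.010456325
CHARGE=1+
RTINSECONDS=1179.60119694
SCANS=32
82.6433642023 1178.12355109
91.5304445712 3285.80566371
98.9841720494 67680.671167
122.772655159 10364.5631558
151.39867953 1189.95127735
195.775152877 2445.99634628
201.027135424 57318.6351492
258.205778166 2820.07397018
258.986959317 1121.96353325
265.514694223 6499.27798563
294.610825991 81421.6865091
314.331578499 10437.9614524
327.716464287 1462.77207464
447.894877479 84600.8389588
464.058350065 3623.71218266
578.414783239 8794.99550743
END IONS

BEGIN IONS
TITLE=/tmp/Rtmpneusco/massql-batch-fixture/synthetic_02.mzML scan=12
PEPMASS=768.769891839
CHARGE=1+
RTINSECONDS=363.361078966
SCANS=12
98.9841720494 43778.4231633
150.092852745 1531.43671443
238.116943469 35152.9310661
255.095803762 33291.5660476
285.980669962 7712.29263365
301.10666476 44496.6958995
326.70149054 54723.0289541
327.303513691 15486.3709638
330.049611792 44885.9410221
373.413032005 43498.9805284
393.662228834 50895.5237817
396.575253518 6558.68192871
527.355996551 1688.88133875
629.62127144 3955.81903006
726.829116009 3802.97316659
730.989312011 44972.6442314
END IONS

BEGIN IONS
TITLE=/tmp/Rtmpneusco/massql-batch-fixture/synthetic_02.mzML scan=33
PEPMASS=653.269124543
CHARGE=1+
RTINSECONDS=1170.02180815
SCANS=33
52.1549400728 25415.0958715
55.6291601266 91441.5039776
62.9244947017 9382.54781252
71.8948479005 9096.06899404
73.3767652789 52539.4788761
98.9841720494 79490.8775767
212.012544748 17034.2164302
300.959507023 22002.9942359
326.799314586 4885.87314587
368.538912404 4292.95940072
369.874573338 43447.5650061
380.84984571 66567.7141728
402.511049 99363.5969709
454.639122218 4372.50975513
456.080072465 36805.9455243
568.005557617 13253.5922365
END IONS

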