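# Frozen oracle values for the Symlet-2 DWT: coefficients of two fixed
# pseudo-random windows computed with an independent reference
# implementation (PyWavelets wavedec, sym2, half-point symmetric extension).
# x50: 50-sample window, 5 levels -> 57 detail + 4 approximation coeffs.
# x13: 13-sample window, 2 levels -> 13 detail coeffs.
wavelet_oracle_x50 <-
c(0.30471707975443135, -1.0399841062404955, 0.75045119580645725, 
0.94056471639121386, -1.9510351886538364, -1.3021795068623181, 
0.12784040316728537, -0.31624259234358221, -0.016801157504288795, 
-0.85304392757358005, 0.87939797486282856, 0.77779193542894831, 
0.066030697561216045, 1.1272412069680329, 0.4675093422520456, 
-0.85929246288323824, 0.36875078408249884, -0.9588826008289989, 
0.87845030130727253, -0.049925910986252896, -0.18486236354526056, 
-0.68092954440394138, 1.2225413386740303, -0.15452948206880215, 
-0.42832782216310722, -0.35213355048822959, 0.53230918555334872, 
0.36544406436407834, 0.4127326115959884, 0.43082100300788273, 
2.1416476008704612, -0.40641501638461558, -0.51224272907153734, 
-0.81377272824787772, 0.61597942257549565, 1.1289722927208916, 
-0.11394745765487507, -0.84015647696252804, -0.82448121569123956, 
0.65059278782470109, 0.74325417120344228, 0.54315426830519498, 
-0.6655097072886943, 0.23216132306671977, 0.11668580914072822, 
0.21868859672901295, 0.87142877794818985, 0.22359554877468227, 
0.67891356307189488, 0.067579069488891461)
wavelet_oracle_det57 <-
c(0.82345794055049104, 0.36717955349263776, -1.3111056810256023, 
0.80403210898118882, 0.45227421047820476, 0.55336487979815041, 
-0.77731970707495557, 0.54487637266969291, 0.90367575280204659, 
0.92615815471740259, 0.071734088085645631, 1.2738569027712521, 
-0.31180741632318865, 0.403147657463027, -0.013610931663846429, 
1.8378290989915462, -0.22153150656524898, 0.21871633641485544, 
-0.022320306065767292, -0.80084235853194441, 0.32029020081655246, 
-0.88676389542116152, 0.026076856524592844, 0.5568580598804167, 
0.3723953267994668, -0.37436439286016709, 0.38690729822775283, 
1.8414187993429174, 0.5473488542906243, 0.36736322565151092, 
-0.42542852756035932, 0.66656954753524, 0.57722131090704398, 
0.017058377044236461, 0.70259370851614855, 1.7255825731730898, 
-0.044845850979882307, -0.47763033998105048, 0.40377069280717531, 
-0.26921571433193064, -0.092049444089300755, -0.65279832062535048, 
1.6385460157585161, 0.013667884491532861, 1.2783901114442711, 
-0.66598212342530805, -0.04415244331236793, 0.11714836918566626, 
0.057129335609770203, -0.58449666094074471, -0.10982614782042564, 
-0.22198651236382844, 0.24966166337847628, 0.12692944977607123, 
6.4708757072512446e-05, 0.205321429283151, 0.11116141952207026
)
wavelet_oracle_a5 <-
c(-0.82341063589802488, -0.93594815766768458, 0.58108071348104162, 
1.3771363320399237)
wavelet_oracle_x13 <-
c(0.28911939868998415, 0.63128822583854038, -1.4571558198556664, 
-0.31967121635730134, -0.47037265429279551, -0.63887784824334193, 
-0.27514225122668373, 1.4949413112343959, -0.86583111569324323, 
0.96827835459148082, -1.6828697716158048, -0.33488502998577485, 
0.16275306510500559)
wavelet_oracle_det13 <-
c(-0.2095347581000721, -1.243459446628187, 0.17530209444881339, 
-0.74809093692769679, -1.4914002800598625, -1.3509978158208402, 
0.35038369762774646, 0.47508500188475483, 0.090250669273826661, 
-0.49467878865880338, 0.9963078824120335, -1.1902687426271275, 
0.87872284942882195)
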