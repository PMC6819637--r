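H CIDH920101
D Normalized hydrophobicity scales for alpha-proteins (Cid et al., 1992)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  -0.450  -0.240  -0.200  -1.520   0.790  -0.990  -0.800  -1.000   1.070   0.760
   1.290  -0.360   1.370   1.480  -0.120   1.380   1.490   1.260  -0.980  -0.700
//
H EISD860103
D Direction of hydrophobic moment (Eisenberg-McLachlan, 1986)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   0.000  -0.960  -0.860  -0.980   0.760  -1.000  -0.890   0.000  -0.750   0.990
   0.890  -0.990   0.940   0.920   0.220   0.670  -0.930   0.840  -0.670   0.090
//
H NISK860101
D 14 A contact number (Nishikawa-Ooi, 1986)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  -0.220  -0.930  -2.650  -4.120   4.660  -2.760  -3.640  -1.620   1.280   5.580
   5.010  -4.180   3.510   5.270  -3.030   5.200   2.150   4.450  -2.840  -1.200
//
H QIAN880105
D Weights for alpha-helix at the window position of -2 (Qian-Sejnowski, 1988)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   0.680  -0.220  -0.090  -0.020  -0.150  -0.150   0.440  -0.730  -0.140  -0.080
   0.610   0.030   0.390   0.060  -0.760   0.200  -0.040   0.120  -0.260  -0.100
//
H ROBB760101
D Information measure for alpha-helix (Robson-Suzuki, 1976)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   6.500  -0.900  -5.100   0.500  -1.300   1.000   7.800  -8.600   1.200   0.600
   3.200   2.300   5.300   1.600  -7.700   1.200  -4.500   1.400  -3.900  -2.600
//
H ROBB760108
D Information measure for turn (Robson-Suzuki, 1976)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  -5.000   2.100   4.200   3.100   4.400   0.400  -4.700   5.700  -0.300  -4.600
  -5.600   1.000  -4.800  -1.800   2.600   3.400   2.900  -6.000   2.600   0.300
//
H ROBB760112
D Information measure for coil (Robson-Suzuki, 1976)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  -2.500  -1.200   4.600   0.000  -4.700  -0.500  -4.400   4.900   1.600  -3.300
  -2.000  -0.800  -4.100  -4.100   5.800   1.200  -0.600  -3.500   2.500   1.700
//
H ROBB760113
D Information measure for loop (Robson-Suzuki, 1976)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  -5.100   2.600   4.700   3.100   3.800   0.200  -5.200   5.600  -0.900  -4.500
  -5.400   1.000  -5.300  -2.400   3.500   2.900   3.200  -6.300   3.200   0.000
//
H CORJ870103
D PRIFT index (Cornette et al., 1987)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  -0.960   0.750  -1.940  -5.680   4.540  -5.300  -3.860  -1.280  -0.620   5.540
   6.810  -5.620   4.760   5.060  -4.470   0.210   3.340   5.390  -1.920  -3.990
//
H CORJ870106
D ALTLS index (Cornette et al., 1987)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  -1.350  -3.890 -10.960 -11.880   4.370  -1.340  -4.560  -5.820   6.540  10.930
   9.880 -11.920   7.470  11.350 -10.860   1.800   7.610   8.200  -6.210  -4.830
//
H CORJ870107
D TOTFT index (Cornette et al., 1987)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  -0.560  -0.260  -2.870  -4.310   1.780  -2.310  -2.350  -1.350   0.810   3.830
   4.090  -4.080   3.110   3.670  -3.220  -0.110   2.170   3.310  -1.850  -1.970
//
H CORJ870108
D TOTLS index (Cornette et al., 1987)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   1.370   1.330   6.290   8.930  -4.470   3.880   4.040   3.390  -1.650  -7.920
  -8.680   7.700  -7.130  -7.960   6.250   0.790  -4.730  -6.940   4.080   4.020
//
H MIYS990104
D Optimized relative partition energies - method C (Miyazawa-Jernigan, 1999)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  -0.040   0.070   0.130   0.190  -0.380   0.140   0.230   0.090  -0.040  -0.340
  -0.370   0.330  -0.300  -0.380   0.190  -0.330  -0.290  -0.290   0.120   0.030
//
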