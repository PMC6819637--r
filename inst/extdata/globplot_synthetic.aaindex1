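H SYNR465101
D SYNTHETIC stand-in for GlobPlot Remark 465 disorder propensity (constructed values)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   0.060   0.180   0.010   0.190  -0.600   0.320   0.300   0.170  -0.300  -0.490
  -0.330   0.220  -0.230  -0.440   0.550  -0.880  -0.510  -0.420   0.140   0.060
//
H SYNDLRX101
D SYNTHETIC stand-in for GlobPlot Deleage/Roux coil-vs-structure propensity (constructed values)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  -0.280  -0.100   0.250   0.220  -0.020  -0.210  -0.330   0.550  -0.120  -0.350
  -0.380  -0.180  -0.300  -0.320   0.520  -0.270   0.050  -0.350   0.340   0.120
//
H SYNBF2S101
D SYNTHETIC stand-in for GlobPlot B-factor(2STD) flexibility propensity (constructed values)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  -0.120   0.180   0.160   0.250  -0.630   0.300   0.450   0.280  -0.080  -0.480
  -0.380   0.400  -0.310  -0.550   0.320  -0.600  -0.350  -0.450   0.220   0.050
//
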