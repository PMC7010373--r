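# Noncentrality parameter lambda solving I_x(a,b;lambda) = 0.10 at x = x_{0.95}(a,b).
# alpha = 0.05 (type I), beta = 0.10 (type II). 6 significant digits, rounded to nearest.
b	a0.5	a1	a1.5	a2	a2.5	a3	a5	a10	a25
1	4.61803e+01	9.00517e+01	1.33936e+02	1.77823e+02	2.21712e+02	2.65601e+02	4.41161e+02	8.80065e+02	2.19678e+03
2	1.93236e+01	3.04220e+01	4.08997e+01	5.11554e+01	6.13048e+01	7.13948e+01	1.11490e+02	2.11206e+02	5.09746e+02
3	1.53086e+01	2.20966e+01	2.82383e+01	3.41350e+01	3.99085e+01	4.56104e+01	6.80824e+01	1.23556e+02	2.89087e+02
4	1.37822e+01	1.90179e+01	2.36054e+01	2.79378e+01	3.21380e+01	3.62590e+01	5.23587e+01	9.17573e+01	2.08805e+02
5	1.29870e+01	1.74388e+01	2.12434e+01	2.47874e+01	2.81929e+01	3.15140e+01	4.43773e+01	7.55652e+01	1.67745e+02
6	1.25009e+01	1.64830e+01	1.98196e+01	2.28917e+01	2.58210e+01	2.86621e+01	3.95760e+01	6.57902e+01	1.42832e+02
7	1.21736e+01	1.58437e+01	1.88700e+01	2.16290e+01	2.42420e+01	2.67637e+01	3.63771e+01	5.92546e+01	1.26087e+02
8	1.19383e+01	1.53865e+01	1.81924e+01	2.07289e+01	2.31168e+01	2.54110e+01	3.40954e+01	5.45774e+01	1.14042e+02
9	1.17611e+01	1.50436e+01	1.76849e+01	2.00552e+01	2.22750e+01	2.43990e+01	3.23869e+01	5.10640e+01	1.04947e+02
10	1.16228e+01	1.47769e+01	1.72907e+01	1.95324e+01	2.16217e+01	2.36137e+01	3.10600e+01	4.83276e+01	9.78285e+01
11	1.15120e+01	1.45636e+01	1.69759e+01	1.91149e+01	2.11002e+01	2.29868e+01	3.00000e+01	4.61356e+01	9.20991e+01
12	1.14212e+01	1.43892e+01	1.67186e+01	1.87739e+01	2.06743e+01	2.24748e+01	2.91336e+01	4.43398e+01	8.73842e+01
13	1.13454e+01	1.42440e+01	1.65045e+01	1.84902e+01	2.03200e+01	2.20489e+01	2.84125e+01	4.28416e+01	8.34334e+01
14	1.12812e+01	1.41211e+01	1.63236e+01	1.82505e+01	2.00207e+01	2.16891e+01	2.78028e+01	4.15723e+01	8.00727e+01
15	1.12262e+01	1.40158e+01	1.61686e+01	1.80453e+01	1.97645e+01	2.13810e+01	2.72807e+01	4.04832e+01	7.71776e+01
20	1.10375e+01	1.36562e+01	1.56397e+01	1.73453e+01	1.88905e+01	2.03304e+01	2.54976e+01	3.67467e+01	6.71490e+01
30	1.08550e+01	1.33096e+01	1.51311e+01	1.66726e+01	1.80510e+01	1.93210e+01	2.37807e+01	3.31188e+01	5.72176e+01
40	1.07660e+01	1.31411e+01	1.48842e+01	1.63462e+01	1.76437e+01	1.88312e+01	2.29461e+01	3.13414e+01	5.22527e+01
50	1.07132e+01	1.30415e+01	1.47383e+01	1.61535e+01	1.74032e+01	1.85419e+01	2.24526e+01	3.02856e+01	4.92627e+01
100	1.06093e+01	1.28456e+01	1.44516e+01	1.57748e+01	1.69308e+01	1.79737e+01	2.14819e+01	2.81960e+01	4.32297e+01
250	1.05479e+01	1.27301e+01	1.42828e+01	1.55519e+01	1.66527e+01	1.76392e+01	2.09095e+01	2.69549e+01	3.95540e+01
500	1.05276e+01	1.26919e+01	1.42270e+01	1.54783e+01	1.65608e+01	1.75288e+01	2.07203e+01	2.65432e+01	3.83154e+01
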