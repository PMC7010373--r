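# Upper alpha=0.05 quantiles x of the central beta distribution, I_x(a,b) = 0.95.
# Reference values, 6 significant digits, last digit rounded to nearest.
b	a0.5	a1	a1.5	a2	a2.5	a3	a5	a10	a25
1	9.02500e-01	9.50000e-01	9.66383e-01	9.74679e-01	9.79692e-01	9.83048e-01	9.89794e-01	9.94884e-01	9.97950e-01
2	6.58372e-01	7.76393e-01	8.31750e-01	8.64650e-01	8.86622e-01	9.02389e-01	9.37150e-01	9.66681e-01	9.86158e-01
3	4.99474e-01	6.31597e-01	7.04013e-01	7.51395e-01	7.85230e-01	8.10745e-01	8.71244e-01	9.28130e-01	9.69022e-01
4	3.99294e-01	5.27129e-01	6.03932e-01	6.57408e-01	6.97399e-01	7.28662e-01	8.07097e-01	8.87334e-01	9.49692e-01
5	3.31756e-01	4.50720e-01	5.26623e-01	5.81803e-01	6.24472e-01	6.58739e-01	7.48632e-01	8.47282e-01	9.29506e-01
6	2.83463e-01	3.93038e-01	4.65976e-01	5.20703e-01	5.64102e-01	5.99689e-01	6.96463e-01	8.09135e-01	9.09126e-01
7	2.47316e-01	3.48164e-01	4.17435e-01	4.70679e-01	5.13741e-01	5.49642e-01	6.50188e-01	7.73308e-01	8.88911e-01
8	2.19284e-01	3.12344e-01	3.77834e-01	4.29136e-01	4.71285e-01	5.06901e-01	6.09138e-01	7.39886e-01	8.69067e-01
9	1.96926e-01	2.83129e-01	3.44972e-01	3.94163e-01	4.35104e-01	4.70087e-01	5.72619e-01	7.08799e-01	8.49712e-01
10	1.78687e-01	2.58866e-01	3.17294e-01	3.64359e-01	4.03954e-01	4.38105e-01	5.40005e-01	6.79913e-01	8.30912e-01
11	1.63528e-01	2.38404e-01	2.93680e-01	3.38681e-01	3.76883e-01	4.10099e-01	5.10752e-01	6.53069e-01	8.12701e-01
12	1.50733e-01	2.20922e-01	2.73308e-01	3.16340e-01	3.53157e-01	3.85390e-01	4.84396e-01	6.28099e-01	7.95094e-01
13	1.39791e-01	2.05817e-01	2.55557e-01	2.96734e-01	3.32202e-01	3.63442e-01	4.60549e-01	6.04844e-01	7.78091e-01
14	1.30326e-01	1.92636e-01	2.39958e-01	2.79396e-01	3.13568e-01	3.43825e-01	4.38883e-01	5.83155e-01	7.61683e-01
15	1.22059e-01	1.81036e-01	2.26143e-01	2.63957e-01	2.96893e-01	3.26193e-01	4.19120e-01	5.62893e-01	7.45857e-01
20	9.26567e-02	1.39108e-01	1.75534e-01	2.06725e-01	2.34411e-01	2.59467e-01	3.41807e-01	4.79012e-01	6.74797e-01
30	6.25175e-02	9.50339e-02	1.21191e-01	1.44090e-01	1.64826e-01	1.83943e-01	2.49305e-01	3.68153e-01	5.65062e-01
40	4.71693e-02	7.21575e-02	9.25215e-02	1.10553e-01	1.27053e-01	1.42414e-01	1.96078e-01	2.98634e-01	4.85211e-01
50	3.78708e-02	5.81551e-02	7.48160e-02	8.96715e-02	1.03353e-01	1.16167e-01	1.61545e-01	2.51097e-01	4.24830e-01
100	1.90711e-02	2.95130e-02	3.82269e-02	4.61073e-02	5.34614e-02	6.04365e-02	8.58514e-02	1.39660e-01	2.61259e-01
250	7.66110e-03	1.19114e-02	1.54926e-02	1.87595e-02	2.18331e-02	2.47712e-02	3.56731e-02	5.98536e-02	1.20972e-01
500	3.83600e-03	5.97355e-03	7.78040e-03	9.43349e-03	1.09931e-02	1.24879e-02	1.80690e-02	3.06519e-02	6.38108e-02
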