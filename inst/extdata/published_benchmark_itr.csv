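# Published per-subject classification accuracy (%) and ITR at 4 s windows
# (1 s gaze shift, 12 classes) on the public 12-class joint frequency-phase
# modulated SSVEP benchmark (10 subjects, 15 trials per class). The printed
# ITR column follows the natural-logarithm convention; used as a regression
# fixture for the itr() unit conversion.
subject,method,accuracy_pct,itr_printed
1,cca,72.22,14.74
2,cca,71.11,14.29
3,cca,97.78,27.90
4,cca,99.44,29.25
5,cca,98.33,28.32
6,cca,100.00,29.82
7,cca,100.00,29.82
8,cca,100.00,29.82
9,cca,100.00,29.82
10,cca,97.22,27.50
1,msi,70.55,14.07
2,msi,67.78,13.00
3,msi,100.00,29.82
4,msi,99.44,29.25
5,msi,98.33,28.32
6,msi,100.00,29.82
7,msi,100.00,29.82
8,msi,100.00,29.82
9,msi,100.00,29.82
10,msi,95.56,26.36
1,mset,93.89,25.30
2,mset,84.44,20.16
3,mset,100.00,29.82
4,mset,100.00,29.82
5,mset,100.00,29.82
6,mset,100.00,29.82
7,mset,86.11,20.99
8,mset,100.00,29.82
9,mset,100.00,29.82
10,mset,98.89,28.77
1,itcca,99.44,29.25
2,itcca,91.11,23.66
3,itcca,100.00,29.82
4,itcca,100.00,29.82
5,itcca,100.00,29.82
6,itcca,100.00,29.82
7,itcca,79.44,17.81
8,itcca,100.00,29.82
9,itcca,100.00,29.82
10,itcca,98.89,28.77
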