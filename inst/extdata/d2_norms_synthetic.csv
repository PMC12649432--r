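instrument,age_lo,age_hi,raw,ss
cp,9,12,0,7.69
cp,9,12,20,15.38
cp,9,12,40,23.08
cp,9,12,60,30.77
cp,9,12,80,38.46
cp,9,12,100,46.15
cp,9,12,120,53.85
cp,9,12,140,61.54
cp,9,12,160,69.23
cp,9,12,180,76.92
cp,9,12,200,84.62
cp,9,12,220,92.31
cp,9,12,240,100
cp,9,12,260,107.69
cp,9,12,280,115.38
cp,9,12,300,123.08
cp,9,12,320,130.77
pct_errors,9,12,0,108.52
pct_errors,9,12,2,104.81
pct_errors,9,12,4,101.11
pct_errors,9,12,6,97.41
pct_errors,9,12,8,93.7
pct_errors,9,12,10,90
pct_errors,9,12,12,86.3
pct_errors,9,12,14,82.59
pct_errors,9,12,16,78.89
pct_errors,9,12,18,75.19
pct_errors,9,12,20,71.48
pct_errors,9,12,22,67.78
pct_errors,9,12,24,64.07
pct_errors,9,12,26,60.37
pct_errors,9,12,28,56.67
pct_errors,9,12,30,52.96
pct_errors,9,12,32,49.26
pct_errors,9,12,34,45.56
pct_errors,9,12,36,41.85
pct_errors,9,12,38,38.15
pct_errors,9,12,40,34.44
pct_errors,9,12,42,30.74
pct_errors,9,12,44,27.04
pct_errors,9,12,46,23.33
pct_errors,9,12,48,19.63
pct_errors,9,12,50,15.93
pct_errors,9,12,52,12.22
pct_errors,9,12,54,8.52
pct_errors,9,12,56,4.81
pct_errors,9,12,58,1.11
pct_errors,9,12,60,-2.59
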