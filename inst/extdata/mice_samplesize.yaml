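# Planning specification for the diabetic-mice slope-interaction example:
# minimal balanced sample sizes for the extended Welch slope test at
# nominal power 0.80.  Keys follow the conventional program-specification
# names (sigsq = error variance, tausq = predictor variance,
# rn21 = allocation ratio n2/n1).
alpha: 0.05
power: 0.80
beta11: 15.9286
beta12: 3.8398
sigsq1: 10124.8980
sigsq2: 9097.9625
tausq1: 31.1111
tausq2: 23.8600
rn21: 1
method: MT
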