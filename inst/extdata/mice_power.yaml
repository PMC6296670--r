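# Achieved power of the observed diabetic-mice design (n1 = 9 diabetic,
# n2 = 25 normal) for detecting the body-weight by group interaction.
alpha: 0.05
n1: 9
n2: 25
beta11: 15.9286
beta12: 3.8398
sigsq1: 10124.8980
sigsq2: 9097.9625
tausq1: 31.1111
tausq2: 23.8600
method: MT
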