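name,formula,parent,expected_rt_min
STR,C17H17Cl2N,STR,10.2
OH-STR (isomer 1),C17H17Cl2NO,STR,6.7
OH-STR (isomer 2),C17H17Cl2NO,STR,8.2
DM-STR+Phe,C25H24Cl2N2O,STR,13.1
DM-STR+Tyr,C25H24Cl2N2O2,STR,12.7
OH-DM-STR+Phe,C25H24Cl2N2O2,STR,12.5
DM-STR (norsertraline),C16H15Cl2N,STR,
OH-DM-STR,C16H15Cl2NO,STR,
CLP,C19H23ClN2,CLP,10.7
DM-CLP,C18H21ClN2,CLP,10.4
OH-CLP (isomer 1),C19H23ClN2O,CLP,6.8
OH-CLP (isomer 2),C19H23ClN2O,CLP,7.0
OH-DM-CLP,C18H21ClN2O,CLP,6.6
didesmethyl-CLP,C17H19ClN2,CLP,
CLP N-oxide,C19H23ClN2O,CLP,
TZN,C19H22ClN5O,TZN,5.5
OH-TZN,C19H22ClN5O2,TZN,6.3
TZN N-oxide,C19H22ClN5O2,TZN,
dihydroxy-TZN,C19H22ClN5O3,TZN,
mCPP,C10H13ClN2,TZN,3.0
OH-mCPP,C10H13ClN2O,TZN,
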