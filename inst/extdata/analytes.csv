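analyte_id,category,group
mephedrone,SC,G1
4-MPD,SC,G1
ethcathinone,SC,G1
methylone,SC,G2
ethylone,SC,G2
eutylone,SC,G2
ephylone,SC,G2
MDPT,SC,G2
dibutylone,SC,G3
MDPV,SC,G4
MDPHP,SC,G4
MPHP,SC,G5
alpha-PVP,SC,G5
TH-PVP,SC,G5
alpha-PVT,SC,G6
caffeine,interferent,
paracetamol,interferent,
benzocaine,interferent,
lidocaine,interferent,
procaine,interferent,
ketamine,interferent,
MDMA,interferent,
MDEA,interferent,
mCPP,interferent,
BZP,interferent,
amphetamine,silent,
methamphetamine,silent,
cocaine,silent,
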