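analyte_id,scan,label,potential_V,sign,rel_amplitude,width_V
mephedrone,anodic,R1,-1.40,reduction,1.0,
mephedrone,anodic,O1,1.19,oxidation,0.8,
mephedrone,cathodic,R1,-1.40,reduction,1.0,
mephedrone,cathodic,R2,-1.60,reduction,0.6,
4-MPD,anodic,R1,-1.40,reduction,1.0,
4-MPD,anodic,O1,1.10,oxidation,0.8,
4-MPD,cathodic,R1,-1.40,reduction,1.0,
4-MPD,cathodic,R2,-1.60,reduction,0.6,
ethcathinone,anodic,R1,-1.40,reduction,1.0,
ethcathinone,cathodic,R1,-1.40,reduction,1.0,
ethcathinone,cathodic,R2,-1.60,reduction,0.6,
methylone,anodic,R1,-1.40,reduction,1.0,
methylone,anodic,O1,0.60,oxidation,0.8,
methylone,anodic,O2,1.00,oxidation,0.8,
methylone,anodic,O3,1.25,oxidation,0.8,
methylone,cathodic,O3,1.30,oxidation,0.8,
methylone,cathodic,R1,-1.40,reduction,1.0,
methylone,cathodic,R2,-1.60,reduction,0.6,
ethylone,anodic,R1,-1.40,reduction,1.0,
ethylone,anodic,O1,0.60,oxidation,0.8,
ethylone,anodic,O2,1.00,oxidation,0.8,
ethylone,anodic,O3,1.25,oxidation,0.8,
ethylone,cathodic,O3,1.30,oxidation,0.8,
ethylone,cathodic,R1,-1.40,reduction,1.0,
ethylone,cathodic,R2,-1.60,reduction,0.6,
eutylone,anodic,R1,-1.40,reduction,1.0,
eutylone,anodic,O1,0.60,oxidation,0.8,
eutylone,anodic,O2,1.00,oxidation,0.8,
eutylone,anodic,O3,1.25,oxidation,0.8,
eutylone,cathodic,O3,1.30,oxidation,0.8,
eutylone,cathodic,R1,-1.40,reduction,1.0,
eutylone,cathodic,R2,-1.60,reduction,0.6,
ephylone,anodic,R1,-1.40,reduction,1.0,
ephylone,anodic,O1,0.60,oxidation,0.8,
ephylone,anodic,O2,1.00,oxidation,0.8,
ephylone,anodic,O3,1.25,oxidation,0.8,
ephylone,cathodic,O3,1.30,oxidation,0.8,
ephylone,cathodic,R1,-1.40,reduction,1.0,
ephylone,cathodic,R2,-1.60,reduction,0.6,
MDPT,anodic,R1,-1.40,reduction,1.0,
MDPT,anodic,O1,0.60,oxidation,0.8,
MDPT,anodic,O2,1.00,oxidation,0.8,
MDPT,anodic,O3,1.25,oxidation,0.8,
MDPT,cathodic,O3,1.30,oxidation,0.8,
MDPT,cathodic,R1,-1.40,reduction,1.0,
MDPT,cathodic,R2,-1.60,reduction,0.6,
dibutylone,anodic,R1,-1.40,reduction,1.0,
dibutylone,anodic,O1,0.60,oxidation,0.8,
dibutylone,anodic,O2,0.83,oxidation,0.8,
dibutylone,anodic,O3,1.03,oxidation,0.8,
dibutylone,anodic,O4,1.19,oxidation,0.8,
dibutylone,cathodic,O4,1.30,oxidation,0.8,
dibutylone,cathodic,O3,1.00,oxidation,0.8,
dibutylone,cathodic,R1,-1.30,reduction,1.0,
dibutylone,cathodic,R2,-1.60,reduction,0.6,
MDPV,anodic,R1,-1.40,reduction,1.0,
MDPV,anodic,O1,0.60,oxidation,0.8,
MDPV,anodic,O2,0.78,oxidation,0.8,
MDPV,anodic,O3,0.90,oxidation,0.8,
MDPV,anodic,O4,1.01,oxidation,0.8,
MDPV,anodic,O5,1.19,oxidation,0.8,
MDPV,cathodic,O5,1.30,oxidation,0.8,
MDPV,cathodic,O4,1.00,oxidation,0.8,
MDPV,cathodic,R1,-1.30,reduction,1.0,
MDPV,cathodic,R2,-1.60,reduction,0.6,
MDPHP,anodic,R1,-1.40,reduction,1.0,
MDPHP,anodic,O1,0.60,oxidation,0.8,
MDPHP,anodic,O2,0.78,oxidation,0.8,
MDPHP,anodic,O3,0.90,oxidation,0.8,
MDPHP,anodic,O4,1.01,oxidation,0.8,
MDPHP,anodic,O5,1.19,oxidation,0.8,
MDPHP,cathodic,O5,1.30,oxidation,0.8,
MDPHP,cathodic,O4,1.00,oxidation,0.8,
MDPHP,cathodic,R1,-1.30,reduction,1.0,
MDPHP,cathodic,R2,-1.60,reduction,0.6,
MPHP,anodic,R1,-1.30,reduction,1.0,
MPHP,anodic,O1,0.90,oxidation,0.8,
MPHP,anodic,O2,1.00,oxidation,0.8,
MPHP,cathodic,O2,1.00,oxidation,0.8,
MPHP,cathodic,R1,-1.30,reduction,1.0,
MPHP,cathodic,R2,-1.60,reduction,0.6,
alpha-PVP,anodic,R1,-1.30,reduction,1.0,
alpha-PVP,anodic,O1,0.90,oxidation,0.8,
alpha-PVP,anodic,O2,1.00,oxidation,0.8,
alpha-PVP,cathodic,O2,1.00,oxidation,0.8,
alpha-PVP,cathodic,R1,-1.30,reduction,1.0,
alpha-PVP,cathodic,R2,-1.60,reduction,0.6,
TH-PVP,anodic,R1,-1.30,reduction,1.0,
TH-PVP,anodic,O1,0.90,oxidation,0.8,
TH-PVP,anodic,O2,1.00,oxidation,0.8,
TH-PVP,cathodic,O2,1.00,oxidation,0.8,
TH-PVP,cathodic,R1,-1.30,reduction,1.0,
TH-PVP,cathodic,R2,-1.60,reduction,0.6,
alpha-PVT,anodic,R1,-1.30,reduction,1.0,
alpha-PVT,anodic,O1,-0.31,oxidation,0.8,
alpha-PVT,anodic,O2,-0.17,oxidation,0.8,
alpha-PVT,anodic,O3,0.82,oxidation,0.8,
alpha-PVT,anodic,O4,0.95,oxidation,0.8,
alpha-PVT,cathodic,O3,1.00,oxidation,0.8,
alpha-PVT,cathodic,O4,1.30,oxidation,0.8,
alpha-PVT,cathodic,R1,-1.22,reduction,1.0,
alpha-PVT,cathodic,R2,-1.47,reduction,0.6,
caffeine,anodic,O1,1.30,oxidation,0.8,
paracetamol,anodic,O1,0.21,oxidation,0.8,
paracetamol,cathodic,Rd1,-0.24,reduction,0.8,
benzocaine,anodic,O1,0.77,oxidation,0.8,
lidocaine,anodic,O1,0.87,oxidation,0.8,
procaine,anodic,O1,0.77,oxidation,0.8,
ketamine,anodic,O1,1.09,oxidation,0.8,
MDMA,anodic,O1,1.00,oxidation,0.8,
MDMA,anodic,O2,1.20,oxidation,0.8,
MDMA,cathodic,Rd1,-0.70,reduction,0.8,
MDMA,cathodic,Rd2,-0.50,reduction,0.8,
MDEA,anodic,O1,1.00,oxidation,0.8,
MDEA,anodic,O2,1.20,oxidation,0.8,
MDEA,cathodic,Rd1,-0.70,reduction,0.8,
MDEA,cathodic,Rd2,-0.50,reduction,0.8,
mCPP,anodic,O1,0.99,oxidation,0.8,
BZP,anodic,O1,0.76,oxidation,0.8,
BZP,anodic,O2,1.00,oxidation,0.8,
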