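subject,R->WF,R->WE,R->WP,R->WS,R->RD,R->UD,R->P,R->F,WF->R,WE->R,WP->R,WS->R,RD->R,UD->R,P->R,F->R
S1,372,318,390,356,296,268,212,284,408,642,468,580,330,728,738,850
S2,618,336,260,290,372,350,368,210,248,602,490,764,300,208,208,954
S3,268,184,288,288,1492,258,154,228,794,840,686,724,118,578,774,810
S4,202,222,238,298,794,228,594,212,774,496,420,648,522,578,534,648
S5,232,422,292,506,292,254,228,192,824,562,684,756,262,596,934,886
S6,716,330,248,552,228,252,134,298,706,724,826,720,700,854,1120,912
S7,438,332,492,364,598,380,228,158,546,344,360,656,262,400,658,624
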