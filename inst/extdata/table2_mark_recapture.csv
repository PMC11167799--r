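release_area,release_region,released,d7a,d7g,d7f,d7h,d7e,d7d,d4c,d4b,d8a,d8b,d8c,ci,note
ICS,7.a,400,1,0,1,1,0,3,0,0,0,0,0,0,
ICS,7.f,313,1,1,1,5,0,2,0,0,0,1,0,0,
EC,7.e,2017,0,0,3,0,75,2,6,6,0,2,1,1,recapture digit run ambiguous; single-digit reading except home division 75
EC,7.d,563,0,0,0,0,8,6,2,0,0,0,0,0,
NS,4.c,205,0,0,0,0,1,3,6,0,0,0,0,0,
NS,4.b,117,1,0,0,0,1,1,3,8,0,0,0,0,
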