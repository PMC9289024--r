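scenario,total_steps,at_risk,unsafe_human,unsafe_original_ai,unsafe_safe_ai
A,984269,29089,15630,NA,NA
B,984269,118869,2986,NA,NA
C,984269,661,356,NA,NA
D,984269,9409,3517,NA,NA
any,984269,NA,21489,20079,18929
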