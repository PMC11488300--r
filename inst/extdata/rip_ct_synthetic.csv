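target,fraction,antibody,ct
rRNA_18S,input,none,17.90
rRNA_18S,input,none,18.10
rRNA_18S,RIP,RIG-I,21.90
rRNA_18S,RIP,RIG-I,22.10
rRNA_18S,NS,IgG,25.20
rRNA_18S,NS,IgG,25.44
TRIM25,input,none,23.95
TRIM25,input,none,24.05
TRIM25,RIP,RIG-I,27.40
TRIM25,RIP,RIG-I,27.60
TRIM25,NS,IgG,30.40
TRIM25,NS,IgG,30.60
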