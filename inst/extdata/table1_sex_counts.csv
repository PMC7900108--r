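group,male,female
HOA,12,9
LLD-MCI-A+,4,22
LLD-MCI-A-,2,25
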