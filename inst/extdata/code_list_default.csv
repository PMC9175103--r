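"code_prefix","group"
"M75","A"
"M25.61","B"
"M24.81","B"
"M25.51","C"
"S43","D"
"S46","D"
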