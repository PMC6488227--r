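SYN0098
SYN0080
SYN0057
SYN0026
ABSENT001
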