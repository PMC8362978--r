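unit,decade,factor
*,1980,1.25
*,1990,1.18
*,2000,1.09
*,2010,1.03
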