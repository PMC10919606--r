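"template_id","primer_set","efficiency"
"gBlock3","DSR1762Fmix/DSR2107Rmix",0.6
"gBlock6","DSR1728Fmix/DSR4Rmix",0.55
"gBlock7","DSR1728Fmix/DSR4Rmix",0.5
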