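"trigger_char","trigger_state","consequences"
"per_presence",0,"per_phyllotaxis|per_merism|per_whorls|per_differentiation|per_fusion|per_symmetry|per_petaloidy|and_per_fusion"
"gyn_carpel_number",0,"gyn_fusion"
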