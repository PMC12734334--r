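field,role,level,code
color,trait,brown,B
color,trait,white,W
origin,supplementary,China,CN
origin,supplementary,Japan,JP
origin,supplementary,Malaysia,MY
origin,supplementary,SoutheastAsia,SE
cultivation,supplementary,industrial,I
cultivation,supplementary,artificial,A
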