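taxon,hybrid
Vitis riparia,FALSE
Vitis labrusca,FALSE
Vitis cinerea,FALSE
Vitis rupestris,FALSE
Vitis acerifolia,FALSE
Vitis amurensis,FALSE
Vitis vulpina,FALSE
Vitis aestivalis,FALSE
Vitis palmata,FALSE
Vitis coignetiae,FALSE
Ampelopsis glandulosa var. brevipedunculata,FALSE
Vitis x andersonii,TRUE
Vitis x champinii,TRUE
Vitis x doaniana,TRUE
Vitis x novae-angliae,TRUE
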