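image_id,role,row,col
cell_01,centrosome,30,46
cell_01,synapse_center,31,50
cell_02,centrosome,28,22
cell_02,synapse_center,33,51
cell_03,centrosome,35,40
cell_03,synapse_center,30,52
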