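,pollinator_01,pollinator_02,pollinator_03,pollinator_04,pollinator_05,pollinator_06,pollinator_07,pollinator_08,pollinator_09,pollinator_10
plant_01,0,1,0,1,0,1,0,1,0,0
plant_02,1,1,0,0,0,0,0,0,1,0
plant_03,1,0,0,0,0,1,0,0,0,1
plant_04,0,0,0,0,0,0,1,0,0,0
plant_05,0,0,0,0,1,0,0,0,0,0
plant_06,0,1,0,0,0,0,0,1,1,1
plant_07,0,0,1,0,1,0,1,0,0,1
plant_08,1,0,0,0,1,1,0,1,0,0
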