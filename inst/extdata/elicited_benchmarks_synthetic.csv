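bioregion,vegetation_class,growth_form,mean,lo10,hi90
bioregion_01,class_01,fern,1,0,2
bioregion_01,class_01,forb,8,5,12
bioregion_01,class_01,grass,6,4,9
bioregion_01,class_01,other,1,0,3
bioregion_01,class_01,shrub,7,4,10
bioregion_01,class_01,tree,2,1,4
bioregion_02,class_03,fern,0,0,1
bioregion_02,class_03,forb,10,6,15
bioregion_02,class_03,grass,8,5,12
bioregion_02,class_03,other,2,0,4
bioregion_02,class_03,shrub,5,3,8
bioregion_02,class_03,tree,3,1,5
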