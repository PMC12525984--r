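crop,stress,greenhouses,rows,images_per_week,weeks,total_images
potato,drought,2,6,30,5,1800
potato,heat,6,1,30,4,720
sweet_potato,drought,1,3,30,11,990
sweet_potato,excess_water,1,3,30,11,990
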