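class,id,ct,t1,t2fs
air,0,-1000,0,0
lung_left,1,-600,5,45
lung_right,2,-600,5,45
fat,3,-120,760,135
muscle,4,160,438,270
liver,5,440,352,450
spleen,6,640,292,568
gallbladder,7,840,231,870
kidney_left,8,1200,122,761
kidney_right,9,1200,122,761
aorta,10,1400,61,225
bone,11,1600,15,90
tumor,12,1040,170,640
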