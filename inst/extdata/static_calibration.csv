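x,y,mean_x,mean_y,sd_x,sd_y,ratio_x,ratio_y,ratio_d
11.5,9.5,11.2,11.6,0.14,0.15,2.6,22,8
5.75,4.75,6.2,5.7,0.45,0.42,8,2,12
11.5,-9.5,12,-11,0.13,0.12,4,15,5
5.75,-4.75,6.4,-5.3,0.15,0.16,11,11,11
-5.75,4.75,-6.9,5.6,0.07,0.05,2,17,18
-11.5,9.5,-11.2,10.6,0.27,0.2,2,12,0
-5.75,-4.75,-7.3,-4.8,0.18,0.17,27,1,16
-11.5,-9.5,-11.2,-10.6,0.23,0.2,3,12,3
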