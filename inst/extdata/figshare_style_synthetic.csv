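worker,cohort,image,order,bid,left,top,w,h,secs
w001,master,img001,1,1,12.5,8.0,30.0,42.0,21.4
w001,master,img001,1,2,60.0,15.5,28.0,40.0,21.4
w001,master,img002,2,1,22.0,30.0,26.5,39.0,18.9
w002,credit,img001,1,1,11.0,9.5,33.0,44.0,35.2
w002,credit,img002,2,1,20.0,28.0,30.0,41.5,27.8
w003,nonmaster,img001,2,1,13.0,7.0,29.0,43.0,24.1
w003,nonmaster,img002,1,1,21.5,29.5,27.0,40.0,26.0
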