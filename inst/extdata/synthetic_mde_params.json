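{"labels":["sadness","anhedonia","appetite","sleep","psychomotor","fatigue","culpability","concentration","suicidal_ideations"],"thresholds":[5.0697375537433,0.892084708003977,-0.346531185895995,0.457897071113146,-0.830922517353986,-0.930847739003548,0.316582387068873,1.03769435058735,-3.11888833480073],"weights":[[0,0,0,0,0,1.35,-1.35,-1.5,1.5],[0,0,0,0,0,1.5,0,0,0],[0,0,0,1.05,0,0,0,0,0],[0,0,1.05,0,0,0,0,0,0],[0,0,0,0,0,0,0,1.2,0],[1.35,1.5,0,0,0,0,0,0,0],[-1.35,0,0,0,0,0,0,1.2,2.1],[-1.5,0,0,0,1.2,0,1.2,0,0],[1.5,0,0,0,0,0,2.1,0,0]]}
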