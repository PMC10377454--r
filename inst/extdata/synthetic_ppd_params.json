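{"labels":["sadness","anhedonia","appetite","sleep","psychomotor","fatigue","culpability","concentration","suicidal_ideations"],"thresholds":[4.13227077423457,3.69511677648561,-0.150648477193213,-1.18683590176872,-0.965204489974873,3.99940739002109,-0.0380256826415632,-0.647569957686638,-3.10481881839389],"weights":[[0,-2.4,0,0,0,0,0,0,1.8],[-2.4,0,0,0,0,0,0,0,0],[0,0,0,1.05,0,0,0,0,0],[0,0,1.05,0,0,0,0,1.2,1.5],[0,0,0,0,0,1.2,0,0,0],[0,0,0,0,1.2,0,0,0,-1.8],[0,0,0,0,0,0,0,0,1.05],[0,0,0,1.2,0,0,0,0,1.35],[1.8,0,0,1.5,0,-1.8,1.05,1.35,0]]}
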