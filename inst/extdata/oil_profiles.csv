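tg,sample,mg_per_g,sd
PPO,RRO,Nd,
PPL,RRO,Nd,
PSO,RRO,Nd,
OOP,RRO,47.4,2.1
POL,RRO,53.3,2.6
POLn,RRO,26.9,1.4
OOS,RRO,13.7,4.1
OOO,RRO,424.1,10.1
OOL,RRO,194.6,8.3
OOLn,RRO,117.8,5.7
LLO,RRO,34.9,2.2
PPO,OO,20.8,2.8
PPL,OO,9.3,4.1
PSO,OO,6.7,0.8
OOP,OO,254.2,8.2
POL,OO,60.6,2.5
POLn,OO,1.6,0.5
OOS,OO,33.3,1.1
OOO,OO,516.5,11.1
OOL,OO,88.5,6.4
OOLn,OO,Nd,
LLO,OO,8.4,0.6
PPO,OO_in_RRO_1,0.8,0.3
PPL,OO_in_RRO_1,0.9,0.2
PSO,OO_in_RRO_1,0.2,0.1
OOP,OO_in_RRO_1,71.5,3.7
POL,OO_in_RRO_1,48.3,2.3
POLn,OO_in_RRO_1,26.1,1.7
OOS,OO_in_RRO_1,11.7,0.8
OOO,OO_in_RRO_1,429.3,9.6
OOL,OO_in_RRO_1,183.3,7.7
OOLn,OO_in_RRO_1,116.8,5.1
LLO,OO_in_RRO_1,32.6,0.9
PPO,OO_in_RRO_2.5,3.9,0.8
PPL,OO_in_RRO_2.5,1.9,0.6
PSO,OO_in_RRO_2.5,1.4,0.5
OOP,OO_in_RRO_2.5,82.4,2.3
POL,OO_in_RRO_2.5,50.1,2.0
POLn,OO_in_RRO_2.5,24.3,1.6
OOS,OO_in_RRO_2.5,14.5,0.8
OOO,OO_in_RRO_2.5,430.2,9.3
OOL,OO_in_RRO_2.5,155.4,7.5
OOLn,OO_in_RRO_2.5,97.3,3.8
LLO,OO_in_RRO_2.5,30.7,1.1
PPO,OO_in_RRO_5,4.3,0.3
PPL,OO_in_RRO_5,2.1,0.1
PSO,OO_in_RRO_5,1.9,0.1
OOP,OO_in_RRO_5,105.7,4.3
POL,OO_in_RRO_5,54.2,3.0
POLn,OO_in_RRO_5,23.0,1.1
OOS,OO_in_RRO_5,20.2,1.4
OOO,OO_in_RRO_5,443.8,8.6
OOL,OO_in_RRO_5,137.7,5.3
OOLn,OO_in_RRO_5,80.8,2.1
LLO,OO_in_RRO_5,28.3,1.1
PPO,OO_in_RRO_10,7.9,0.3
PPL,OO_in_RRO_10,2.7,0.1
PSO,OO_in_RRO_10,5.8,0.3
OOP,OO_in_RRO_10,124.7,5.6
POL,OO_in_RRO_10,42.4,2.0
POLn,OO_in_RRO_10,18.9,0.9
OOS,OO_in_RRO_10,23.3,1.1
OOO,OO_in_RRO_10,470.0,10.8
OOL,OO_in_RRO_10,121.5,6.2
OOLn,OO_in_RRO_10,68.2,3.1
LLO,OO_in_RRO_10,24.9,0.9
PPO,RRO_in_OO_1,18.4,0.8
PPL,RRO_in_OO_1,8.5,0.4
PSO,RRO_in_OO_1,7.6,0.3
OOP,RRO_in_OO_1,246.5,8.7
POL,RRO_in_OO_1,55.2,2.7
POLn,RRO_in_OO_1,2.8,0.1
OOS,RRO_in_OO_1,33.2,1.4
OOO,RRO_in_OO_1,515.6,8.8
OOL,RRO_in_OO_1,83.6,5.7
OOLn,RRO_in_OO_1,2.2,0.1
LLO,RRO_in_OO_1,8.7,1.1
PPO,RRO_in_OO_2.5,17.0,0.5
PPL,RRO_in_OO_2.5,8.4,0.3
PSO,RRO_in_OO_2.5,6.0,0.4
OOP,RRO_in_OO_2.5,235.0,7.1
POL,RRO_in_OO_2.5,49.0,2.3
POLn,RRO_in_OO_2.5,4.9,0.2
OOS,RRO_in_OO_2.5,31.7,1.8
OOO,RRO_in_OO_2.5,507.8,9.8
OOL,RRO_in_OO_2.5,91.0,4.5
OOLn,RRO_in_OO_2.5,4.1,0.3
LLO,RRO_in_OO_2.5,9.4,0.5
PPO,RRO_in_OO_5,15.0,0.8
PPL,RRO_in_OO_5,8.1,0.5
PSO,RRO_in_OO_5,4.1,0.5
OOP,RRO_in_OO_5,212.0,9.6
POL,RRO_in_OO_5,43.3,2.1
POLn,RRO_in_OO_5,6.4,0.2
OOS,RRO_in_OO_5,29.7,1.2
OOO,RRO_in_OO_5,504.9,10.6
OOL,RRO_in_OO_5,107.6,5.2
OOLn,RRO_in_OO_5,6.0,0.4
LLO,RRO_in_OO_5,9.9,0.5
PPO,RRO_in_OO_10,12.4,0.6
PPL,RRO_in_OO_10,7.4,0.4
PSO,RRO_in_OO_10,3.9,0.2
OOP,RRO_in_OO_10,190.9,10.1
POL,RRO_in_OO_10,43.7,1.9
POLn,RRO_in_OO_10,11.7,0.3
OOS,RRO_in_OO_10,22.5,0.9
OOO,RRO_in_OO_10,500.2,9.9
OOL,RRO_in_OO_10,114.3,4.6
OOLn,RRO_in_OO_10,12.2,0.6
LLO,RRO_in_OO_10,12.7,0.6
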