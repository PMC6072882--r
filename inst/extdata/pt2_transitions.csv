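subject,R->WF,R->WE,R->WP,R->WS,R->RD,R->UD,R->P,R->F,WF->R,WE->R,WP->R,WS->R,RD->R,UD->R,P->R,F->R
S1,-404,-386,-256,-284,-498,-708,-574,-456,-580,-350,-286,-376,-428,-298,-294,26
S2,-182,-298,-324,-288,-222,-376,-518,-510,-466,-266,-194,-162,-404,-570,-708,-104
S3,-372,-384,-254,-220,832,-358,-396,-462,-64,98,76,20,-962,-278,78,100
S4,-302,-196,-126,-322,138,-480,-18,-588,-46,44,-38,-4,-460,-230,-104,44
S5,-462,-358,-268,-246,-326,-436,-408,-776,50,-194,10,14,-602,-74,220,-36
S6,-184,-360,-308,-80,-444,-484,-594,-480,-86,-82,150,10,-192,184,102,-50
S7,-240,-454,-264,-332,-172,-312,-440,-446,-260,-542,-384,18,-480,-296,64,-34
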