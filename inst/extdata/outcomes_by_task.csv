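team,task,correct,incorrect,ambiguous,no_response
USA,math problems,6,1,5,19
Germany,math problems (Morse-code eye movements),0,0,0,4
Germany,math problems (LR eye movements),1,2,2,45
France,counting (tactile),7,2,2,2
France,sound discrimination,0,0,2,2
France,light discrimination,0,0,0,4
France,semantic discrimination,12,0,14,13
France,yes/no questions,2,0,2,1
Netherlands,math problems,1,0,1,6
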