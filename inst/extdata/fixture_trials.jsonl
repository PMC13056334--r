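{"participant":"P1","session":1,"block":"t1","task":{"start":"ABAB","goal":"A","ruleset_id":"F"},"events":{"t":[1,1.5,1.6,4,4.4,4.5,6,6.5,6.6],"kind":["rule_activate","symbol_activate","state_change","symbol_activate","rule_activate","state_change","rule_activate","symbol_activate","state_change"],"rule":[1,null,1,null,1,1,2,null,2],"pos":[null,0,0,1,null,1,null,0,0],"state":[null,null,"CAB",null,null,"CC",null,null,"A"],"x":[100,400,null,440,240,null,96,396,null],"y":[500,500,null,500,500,null,500,500,null]},"solved":true,"steps":3,"score":228,"group":"A"}
{"participant":"P2","session":1,"block":"t1","task":{"start":"ABAB","goal":"A","ruleset_id":"F"},"events":{"t":[2,2.5,5,5.5,5.6,8,8.5,8.6,10,12,12.5,12.6,14,14.5,14.6,16,16.4,16.5],"kind":["rule_activate","symbol_activate","rule_activate","symbol_activate","state_change","symbol_activate","rule_activate","state_change","reset","rule_activate","symbol_activate","state_change","rule_activate","symbol_activate","state_change","rule_activate","symbol_activate","state_change"],"rule":[2,null,1,null,1,null,3,3,null,1,null,1,1,null,1,2,null,2],"pos":[null,0,null,2,2,1,null,1,null,null,0,0,null,1,1,null,0,0],"state":[null,null,null,null,"ABC",null,null,"AB",null,null,null,"CAB",null,null,"CC",null,null,"A"],"x":[100,400,100,492,null,430,130,null,null,100,400,null,103,403,null,100,400,null],"y":[500,500,500,500,null,500,500,null,null,500,500,null,500,500,null,500,500,null]},"solved":true,"steps":5,"score":117,"group":"A"}
{"participant":"P3","session":1,"block":"t1","task":{"start":"ABAB","goal":"A","ruleset_id":"F"},"events":{"t":[3,3.5,3.6,70,70.5],"kind":["rule_activate","symbol_activate","state_change","symbol_activate","rule_activate"],"rule":[1,null,1,null,2],"pos":[null,0,0,0,null],"state":[null,null,"CAB",null,null],"x":[100,400,null,400,100],"y":[500,500,null,500,500]},"solved":false,"steps":1,"score":0,"group":"A"}
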