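(((L5:0.2408961016,L4:0.2408961016):0.3723992059,L6:0.6132953075):1.964215295,((L3:0.8753302462,L7:0.8753302462):0.2896092835,(L8:0.8891912983,(L1:0.07010698516,L2:0.07010698516):0.8190843131):0.2757482314):1.412571073);
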