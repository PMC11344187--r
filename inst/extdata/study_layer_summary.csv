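layer,n_posts,nodes,edges
P,1283,11087,23504
H,1322,14037,33520
A,387,5477,8696
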