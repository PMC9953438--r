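taxon,cluster
cantabricum,1
crassifolium,2
delarbrei,3
ruscinonense,4
ircutianum,1
leucolepis,5
meridionale,3
pseudosylvaticum,6
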