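taxon,cantabricum,crassifolium,delarbrei,ruscinonense,ircutianum,leucolepis,meridionale,pseudosylvaticum
cantabricum,,0.52,0,0.32,0,0,n/a,0
crassifolium,0.31,,0,0,0,0,n/a,0
delarbrei,0,0,,0,0,0,n/a,0
ruscinonense,0.52,0,0,,0,0,n/a,0
ircutianum,0,0,0,0,,0,n/a,0
leucolepis,0,0,0,0,0,,n/a,0
meridionale,n/a,n/a,n/a,n/a,n/a,n/a,,n/a
pseudosylvaticum,0,0,0,0,0,0,n/a,
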