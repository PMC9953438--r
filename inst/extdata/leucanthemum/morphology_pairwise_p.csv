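taxon,cantabricum,crassifolium,delarbrei,ruscinonense,ircutianum,leucolepis,meridionale,pseudosylvaticum
cantabricum,,<0.01,0.21,<0.01,<0.01,<0.01,<0.01,<0.01
crassifolium,1.0/1.0,,<0.01,<0.01,<0.01,<0.01,<0.01,<0.01
delarbrei,1.0/1.0,0.44/1.0,,<0.01,<0.01,<0.01,1.0,<0.01
ruscinonense,0.04/<0.01,0.02/<0.01,1.0/1.0,,<0.01,<0.01,<0.01,<0.01
ircutianum,<0.01/<0.01,0.17/<0.01,0.02/0.83,<0.01/<0.01,,1.0,<0.01,<0.01
leucolepis,<0.01/<0.01,<0.01/<0.01,<0.01/<0.01,<0.01/<0.01,1.0/<0.01,,<0.01,<0.01
meridionale,1.0/1.0,1.0/1.0,1.0/0.83,1.0/1.0,1.0/<0.01,0.38/<0.01,,<0.01
pseudosylvaticum,<0.01/<0.01,<0.01/<0.01,0.06/<0.01,0.01/<0.01,<0.01/<0.01,<0.01/<0.01,1.0/1.0,
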