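code,name,level1_code,level1_name
1.1,Boreal forest,1,Forest
1.4,Temperate forest,1,Forest
1.5,Subtropical/tropical dry forest,1,Forest
1.6,Subtropical/tropical moist lowland forest,1,Forest
1.9,Subtropical/tropical moist montane forest,1,Forest
2.1,Dry savanna,2,Savanna
2.2,Moist savanna,2,Savanna
3.4,Temperate shrubland,3,Shrubland
4.4,Temperate grassland,4,Grassland
5.1,Permanent rivers,5,Wetlands (inland)
5.4,Bogs and marshes,5,Wetlands (inland)
8.2,Temperate desert,8,Desert
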