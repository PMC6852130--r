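species,growth_form
Acacia deanei,shrub
Austrostipa scabra,grass
Calotis cuneifolia,forb
Cheilanthes sieberi,fern
Eucalyptus populnea,tree
Einadia nutans,forb
Themeda triandra,grass
Cymbopogon refractus,grass
Dodonaea viscosa,shrub
Callitris glaucophylla,tree
Sclerolaena muricata,other
Marsilea drummondii,fern
Oxalis perennans,forb
Rytidosperma caespitosum,grass
Senna artemisioides,shrub
Alectryon oleifolius,tree
Maireana microphylla,other
Boerhavia dominii,forb
Enteropogon acicularis,grass
Geijera parviflora,tree
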