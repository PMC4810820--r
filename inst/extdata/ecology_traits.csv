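species,symbiont,habitat_depth,geographic_range
Globigerina bulloides,none,mixed layer,mid
Globigerinella siphonifera,chrysophytes,mixed layer/thermocline,low-mid
Globigerinoides conglobatus,dinoflagellates,mixed layer,low
Globigerinoides ruber,dinoflagellates,mixed layer,low
Globoconella inflata,chrysophytes,thermocline,low-high
Globorotalia tumida,none,thermocline/sub-thermocline,low
Hirsutella hirsuta,none,thermocline/sub-thermocline,low-mid
Menardella menardii,chrysophytes,thermocline,low
Neogloboquadrina dutertrei,chrysophytes,mixed layer/thermocline,low
Neogloboquadrina pachyderma,none,mixed layer/thermocline,low-high
Pulleniatina obliquiloculata,chrysophytes,mixed layer/thermocline,low
Sphaeroidinella dehiscens,dinoflagellates,thermocline,low
Trilobatus sacculifer,dinoflagellates,mixed layer,low
Truncorotalia crassaformis,none,sub-thermocline,low-mid
Truncorotalia truncatulinoides,none,sub-thermocline,low
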