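"habitat_label","component","oc_stock_kgCm2","oc_accumulation_kgCm2yr"
"Unknown low carbon capacity habitat","combined","0.00","0.000"
"Littoral rock and other hard substrata","combined","0.51","0.340"
"Littoral coarse sediment","combined","n.d","n.d"
"Littoral sand, muddy sand","combined","6.50","0.045"
"Littoral mud","combined","19.90","0.084"
"Littoral mixed sediments","combined","n.d","n.d"
"Coastal saltmarshes and saline reedbeds","combined","27.11","0.263"
"Littoral sediments dominated by aquatic angiosperms","combined","21.33","0.360"
"Sublittoral coarse sediment","combined","n.d","n.d"
"Sublittoral sand","combined","1.70","0.030"
"Sublittoral mud","combined","5.55","0.044"
"Sublittoral mixed sediments","combined","n.d","n.d"
"Biogenic reefs","combined","n.d","n.d"
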