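[{"key":"CO|CO|1-2","name":"CO","formula":"CO"},{"key":"H2|HH|1-2","name":"H2","formula":"H2"},{"key":"H2O|HHO|1-3,2-3","name":"H2O","formula":"H2O"},{"key":"H3N|HHHN|1-4,2-4,3-4","name":"NH3","formula":"H3N"},{"key":"CH2O|CHHO|1-2,1-3,1-4","name":"CH2O","formula":"CH2O"},{"key":"CHN|CHN|1-2,1-3","name":"HCN","formula":"CHN"},{"key":"CH2O2|CHHOO|1-2,1-4,1-5,3-5","name":"HCOOH","formula":"CH2O2"},{"key":"CH3N|CHHHN|1-2,1-3,1-5,4-5","name":"formaldimine","formula":"CH3N"},{"key":"CH4O|CHHHHO|1-2,1-3,1-4,1-6,5-6","name":"CH3OH","formula":"CH4O"},{"key":"CO2|COO|1-2,1-3","name":"CO2","formula":"CO2"}]
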