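[{"id":"extracellular","shape":"rectangle","center":[8,8],"size":[16,16],"base":"rectangle","movable":false,"tags":"extracellular","exclude":["plasma_membrane","cytoplasm_full"]},{"id":"plasma_membrane","shape":"annulus","center":[8,8],"size":[12,12],"inner_size":[10,10],"base":"rectangle","movable":false,"tags":"plasma_membrane","exclude":[],"within":"extracellular"},{"id":"cytoplasm_full","shape":"rectangle","center":[8,8],"size":[12,12],"base":"rectangle","movable":false,"tags":[],"exclude":[],"within":"extracellular"},{"id":"cytoplasm","shape":"rectangle","center":[8,8],"size":[10,10],"base":"rectangle","movable":false,"tags":"cytoplasm","exclude":["nucleus","mitochondria"],"within":"plasma_membrane"},{"id":"nucleus","shape":"oval","center":[8,5.28],"size":[5.44,4.8],"base":"rectangle","movable":true,"tags":"nucleus","exclude":[],"within":"cytoplasm"},{"id":"mitochondria","shape":"oval","center":[4.8,11.52],"size":[3.52,3.2],"base":"rectangle","movable":true,"tags":"mitochondria","exclude":[],"within":"cytoplasm"}]
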