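{"nodes":[{"id":"n01","label":"n01","localization":"cytoplasm"},{"id":"n02","label":"n02","localization":"cytoplasm"},{"id":"n03","label":"n03","localization":"plasma_membrane"},{"id":"n04","label":"n04","localization":"cytoplasm"},{"id":"n05","label":"n05","localization":"cytoplasm"},{"id":"n06","label":"n06","localization":"mitochondria"},{"id":"n07","label":"n07","localization":"cytoplasm"},{"id":"n08","label":"n08","localization":"cytoplasm"},{"id":"n09","label":"n09","localization":"cytoplasm"},{"id":"n10","label":"n10","localization":"cytoplasm"},{"id":"n11","label":"n11","localization":"mitochondria"},{"id":"n12","label":"n12","localization":"cytoplasm"},{"id":"n13","label":"n13","localization":"nucleus"},{"id":"n14","label":"n14","localization":"cytoplasm"},{"id":"n15","label":"n15","localization":"extracellular"},{"id":"n16","label":"n16","localization":"nucleus"},{"id":"n17","label":"n17","localization":"extracellular"},{"id":"n18","label":"n18","localization":"mitochondria"},{"id":"n19","label":"n19","localization":"nucleus"},{"id":"n20","label":"n20","localization":"plasma_membrane"},{"id":"n21","label":"n21","localization":"plasma_membrane"},{"id":"n22","label":"n22","localization":"cytoplasm"},{"id":"n23","label":"n23","localization":"extracellular"},{"id":"n24","label":"n24","localization":"cytoplasm"}],"edges":[["n01","n02"],["n01","n03"],["n01","n04"],["n01","n05"],["n01","n07"],["n01","n12"],["n01","n16"],["n01","n19"],["n01","n21"],["n02","n05"],["n03","n12"],["n03","n13"],["n03","n16"],["n03","n18"],["n04","n06"],["n04","n08"],["n04","n10"],["n04","n14"],["n05","n12"],["n05","n15"],["n05","n17"],["n05","n20"],["n05","n22"],["n05","n23"],["n05","n24"],["n06","n11"],["n08","n09"],["n18","n22"]]}
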