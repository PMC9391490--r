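taxon,diet,body_mass_kg,longevity_days,longevity_is_min,rate_days,rate_is_min
Mesenosaurus,hypercarnivore,5,75,FALSE,38,FALSE
Dimetrodon,hypercarnivore,150,459,FALSE,105,FALSE
Watongia,carnivore,120,145,TRUE,81,TRUE
Haptodus,carnivore,25,152,FALSE,152,TRUE
Oromycter,herbivore,4,506,FALSE,391,FALSE
Ennatosaurus,herbivore,250,628,FALSE,459,FALSE
Edaphosaurus,herbivore,150,506,FALSE,381,FALSE
Delorhynchus,insectivore,0.2,147,FALSE,104,FALSE
Colobomycter,insectivore,0.3,157,FALSE,98,FALSE
Captorhinus,omnivore,1.5,146,FALSE,77,FALSE
Opisthodontosaurus,insectivore,0.4,258,FALSE,188,FALSE
Seymouria,carnivore,5,171,FALSE,135,FALSE
Varanus_bengalensis,carnivore,7,188,FALSE,110,FALSE
Varanus_komodoensis,hypercarnivore,80,227,FALSE,NA,FALSE
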