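((((Delorhynchus:6,Colobomycter:6):20,((Captorhinus:3,Opisthodontosaurus:3):13,(Varanus_bengalensis:30,Varanus_komodoensis:30):275):10):10,((Oromycter:11,Ennatosaurus:32):18,((Mesenosaurus:1,Watongia:18):22,(Edaphosaurus:28,(Haptodus:2,Dimetrodon:23):2):4):6):7):10,Seymouria:55);
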