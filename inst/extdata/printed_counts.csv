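taxon,specimen,element,position,functional_lines,replacement_lines,estimated_lines,printed_rate,method,is_minimum,expected_discrepancy,note
Mesenosaurus efremovi,ROMVP 85502,dentary,NA,NA,NA,NA,39,direct,FALSE,FALSE,rate published without per-tooth counts
Mesenosaurus efremovi,ROMVP 85443,maxilla,NA,NA,NA,NA,34,direct,FALSE,FALSE,rate published without per-tooth counts; left maxilla TR sections
Mesenosaurus efremovi,ROMVP 85457,maxilla,mx10,NA,NA,NA,46,direct,FALSE,FALSE,rate published without per-tooth counts
Mesenosaurus efremovi,ROMVP 85457,maxilla,mx12,NA,NA,NA,36,direct,FALSE,FALSE,rate published without per-tooth counts
Mesenosaurus efremovi,ROMVP 85457,maxilla,mx15,NA,NA,NA,35,direct,FALSE,FALSE,rate published without per-tooth counts
Dimetrodon cf. limbatus,ROMVP 85510,maxilla,NA,459,354,NA,105,direct,FALSE,FALSE,functional 459 and replacement 354 lines published
Haptodus sp.,Hap-UTM-001,maxilla,NA,152,NA,NA,152,minimum,TRUE,FALSE,no replacement tooth and no resorption pit; rate is a lower bound
Watongia meieri,OMNH holotype,maxilla,mx19,81,NA,NA,NA,none,TRUE,FALSE,crown apex missing; minimum age only; resorption pit present but no published estimate
Watongia meieri,OMNH holotype,maxilla,mx19-adjacent,68,NA,NA,NA,none,TRUE,FALSE,crown apex missing; minimum age only; not under replacement
Watongia meieri,OMNH holotype,maxilla,mx18,145,NA,NA,NA,none,FALSE,FALSE,second tooth with resorption pit; age published without rate
Watongia meieri,OMNH holotype,maxilla,complete,108,NA,NA,NA,none,FALSE,FALSE,complete tooth without resorption pit; LL section
Oromycter sp.,ROMVP 85516,maxilla,mx07,506,NA,115,391,rp_height,FALSE,TRUE,text attributes the 115-line estimate to the mx09 family but only the 506-line mx07 tooth gives the published 391; fixture follows the arithmetic
Oromycter sp.,ROMVP 85516,maxilla,mx09,426,NA,NA,NA,none,FALSE,FALSE,tooth without resorption pit; age published without rate
Ennatosaurus tecton,PIN 4543,dentary,d07,567,NA,136,431,rp_height,FALSE,FALSE,pit-estimated replacement count 136 published
Ennatosaurus tecton,PIN 4543,dentary,d08,628,NA,169,459,rp_height,FALSE,FALSE,pit-estimated replacement count 169 published; larger pit
Edaphosaurus sp.,USNM PAL 706602,maxilla,mx09,506,NA,131,381,rp_height,FALSE,TRUE,published rate 381 inconsistent with published counts (506-131=375)
Edaphosaurus sp.,USNM PAL 706602,maxilla,mx10,429,NA,NA,NA,none,FALSE,FALSE,adjacent tooth without resorption pit
Delorhynchus sp.,ROMVP 85513,maxilla,NA,147,43,NA,104,direct,FALSE,FALSE,functional 147 and replacement 43 lines published
Colobomycter sp.,ROMVP 85521,premaxilla,NA,157,59,NA,98,direct,FALSE,FALSE,functional 157 and replacement 59 lines published
Captorhinus sp.,ROMVP 85525,premaxilla,NA,146,69,NA,77,direct,FALSE,FALSE,functional 146 and replacement 69 lines published
Opisthodontosaurus sp.,ROMVP 85511,dentary,d04,151,NA,NA,NA,none,FALSE,FALSE,maximum tooth age published without rate
Opisthodontosaurus sp.,ROMVP 85511,dentary,d05,155,NA,NA,NA,none,FALSE,FALSE,maximum tooth age published without rate
Opisthodontosaurus sp.,ROMVP 85511,dentary,d06,206,NA,24,182,rp_height,FALSE,FALSE,estimated replacement count back-computed from published rate 182
Opisthodontosaurus sp.,ROMVP 85511,dentary,d07,258,NA,65,193,rp_height,FALSE,FALSE,estimated replacement count back-computed from published rate 193
Seymouria sp.,ROMVP 85515,dentary,NA,171,NA,36,135,rp_height,FALSE,FALSE,pit-estimated replacement count 36 published
Varanus bengalensis,ROM R271,maxilla,mx04,188,NA,78,110,dentine_extent,FALSE,FALSE,replacement age from dentine extent over mean line width; estimated count back-computed from published rate 110
Varanus komodoensis,Toronto Zoo,maxilla,attachment-1,106,NA,NA,NA,none,FALSE,FALSE,isolated tooth at attachment stage; age 106 lines
Varanus komodoensis,Toronto Zoo,maxilla,attachment-2,135,NA,NA,NA,none,FALSE,FALSE,isolated tooth at attachment stage; age approximately 135 lines
Varanus komodoensis,Toronto Zoo,maxilla,shed,227,NA,NA,NA,none,FALSE,FALSE,isolated shed tooth; age approximately 227 lines
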