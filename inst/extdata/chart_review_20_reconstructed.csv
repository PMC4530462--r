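"chart_id","algorithm_label","expert_label"
"P01","DRY_AMD","DRY_AMD"
"P02","DRY_AMD","DRY_AMD"
"P03","DRY_AMD","DRY_AMD"
"P04","DRY_AMD","DRY_AMD"
"P05","DRY_AMD","DRY_AMD"
"P06","DRY_AMD","NOT_AMD"
"P07","DRY_AMD","NOT_AMD"
"P08","DRY_AMD","NOT_AMD"
"P09","DRY_AMD","WET_AMD"
"P10","DRY_AMD","WET_AMD"
"P11","WET_AMD","WET_AMD"
"P12","WET_AMD","WET_AMD"
"P13","WET_AMD","WET_AMD"
"P14","WET_AMD","WET_AMD"
"P15","WET_AMD","NOT_AMD"
"P16","WET_AMD","NOT_AMD"
"P17","WET_AMD","NOT_AMD"
"P18","WET_AMD","NOT_AMD"
"P19","WET_AMD","NOT_AMD"
"P20","WET_AMD","DRY_AMD"
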