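"chart_id","algorithm_label","expert_label"
"V001","DRY_AMD","DRY_AMD"
"V002","DRY_AMD","DRY_AMD"
"V003","DRY_AMD","DRY_AMD"
"V004","DRY_AMD","DRY_AMD"
"V005","DRY_AMD","DRY_AMD"
"V006","DRY_AMD","DRY_AMD"
"V007","DRY_AMD","DRY_AMD"
"V008","DRY_AMD","DRY_AMD"
"V009","DRY_AMD","DRY_AMD"
"V010","DRY_AMD","DRY_AMD"
"V011","DRY_AMD","DRY_AMD"
"V012","DRY_AMD","DRY_AMD"
"V013","DRY_AMD","DRY_AMD"
"V014","DRY_AMD","DRY_AMD"
"V015","DRY_AMD","DRY_AMD"
"V016","DRY_AMD","DRY_AMD"
"V017","DRY_AMD","DRY_AMD"
"V018","DRY_AMD","DRY_AMD"
"V019","DRY_AMD","DRY_AMD"
"V020","DRY_AMD","DRY_AMD"
"V021","DRY_AMD","DRY_AMD"
"V022","DRY_AMD","DRY_AMD"
"V023","DRY_AMD","WET_AMD"
"V024","DRY_AMD","WET_AMD"
"V025","DRY_AMD","WET_AMD"
"V026","DRY_AMD","WET_AMD"
"V027","DRY_AMD","NOT_AMD"
"V028","DRY_AMD","NOT_AMD"
"V029","DRY_AMD","NOT_AMD"
"V030","DRY_AMD","NOT_AMD"
"V031","WET_AMD","DRY_AMD"
"V032","WET_AMD","DRY_AMD"
"V033","WET_AMD","DRY_AMD"
"V034","WET_AMD","WET_AMD"
"V035","WET_AMD","WET_AMD"
"V036","WET_AMD","WET_AMD"
"V037","WET_AMD","WET_AMD"
"V038","WET_AMD","WET_AMD"
"V039","WET_AMD","WET_AMD"
"V040","WET_AMD","WET_AMD"
"V041","WET_AMD","WET_AMD"
"V042","WET_AMD","WET_AMD"
"V043","WET_AMD","WET_AMD"
"V044","WET_AMD","WET_AMD"
"V045","WET_AMD","WET_AMD"
"V046","WET_AMD","WET_AMD"
"V047","WET_AMD","WET_AMD"
"V048","WET_AMD","WET_AMD"
"V049","WET_AMD","WET_AMD"
"V050","WET_AMD","WET_AMD"
"V051","WET_AMD","WET_AMD"
"V052","WET_AMD","WET_AMD"
"V053","WET_AMD","WET_AMD"
"V054","WET_AMD","WET_AMD"
"V055","WET_AMD","WET_AMD"
"V056","WET_AMD","WET_AMD"
"V057","WET_AMD","WET_AMD"
"V058","WET_AMD","WET_AMD"
"V059","WET_AMD","WET_AMD"
"V060","WET_AMD","NOT_AMD"
"V061","CONTROL","WET_AMD"
"V062","CONTROL","NOT_AMD"
"V063","CONTROL","NOT_AMD"
"V064","CONTROL","NOT_AMD"
"V065","CONTROL","NOT_AMD"
"V066","CONTROL","NOT_AMD"
"V067","CONTROL","NOT_AMD"
"V068","CONTROL","NOT_AMD"
"V069","CONTROL","NOT_AMD"
"V070","CONTROL","NOT_AMD"
"V071","CONTROL","NOT_AMD"
"V072","CONTROL","NOT_AMD"
"V073","CONTROL","NOT_AMD"
"V074","CONTROL","NOT_AMD"
"V075","CONTROL","NOT_AMD"
"V076","CONTROL","NOT_AMD"
"V077","CONTROL","NOT_AMD"
"V078","CONTROL","NOT_AMD"
"V079","CONTROL","NOT_AMD"
"V080","CONTROL","NOT_AMD"
"V081","CONTROL","NOT_AMD"
"V082","CONTROL","NOT_AMD"
"V083","CONTROL","NOT_AMD"
"V084","CONTROL","NOT_AMD"
"V085","CONTROL","NOT_AMD"
"V086","CONTROL","NOT_AMD"
"V087","CONTROL","NOT_AMD"
"V088","CONTROL","NOT_AMD"
"V089","CONTROL","NOT_AMD"
"V090","CONTROL","NOT_AMD"
"V091","CONTROL","NOT_AMD"
"V092","CONTROL","NOT_AMD"
"V093","CONTROL","NOT_AMD"
"V094","CONTROL","NOT_AMD"
"V095","CONTROL","NOT_AMD"
"V096","CONTROL","NOT_AMD"
"V097","CONTROL","NOT_AMD"
"V098","CONTROL","NOT_AMD"
"V099","CONTROL","NOT_AMD"
"V100","CONTROL","NOT_AMD"
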