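marker,fungal,gram_positive,bacterial,general,primary_group
"18:1w9c",TRUE,FALSE,FALSE,FALSE,fungal
"18:2w6,9",TRUE,FALSE,FALSE,FALSE,fungal
"a15:0",FALSE,TRUE,FALSE,FALSE,bacterial
"i16:0",FALSE,TRUE,FALSE,FALSE,bacterial
"16:1w7",FALSE,TRUE,TRUE,FALSE,bacterial
"10Me16:0",FALSE,TRUE,FALSE,FALSE,bacterial
"a17:0",FALSE,TRUE,FALSE,FALSE,bacterial
"cy17:0",FALSE,TRUE,TRUE,FALSE,bacterial
"10Me18:0",FALSE,TRUE,FALSE,FALSE,bacterial
"cy19:0",FALSE,FALSE,TRUE,FALSE,bacterial
"15:0",FALSE,FALSE,FALSE,TRUE,general
"16:1w5",FALSE,FALSE,FALSE,TRUE,general
"16:1w9",FALSE,FALSE,FALSE,TRUE,general
"18:1w9t",FALSE,FALSE,FALSE,TRUE,general
"19:1w9",FALSE,FALSE,FALSE,TRUE,general
"16:0",FALSE,FALSE,FALSE,TRUE,general
"17:0",FALSE,FALSE,FALSE,TRUE,general
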