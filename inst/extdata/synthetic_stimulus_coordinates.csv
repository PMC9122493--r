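"label","lum","lm","s","contrast_L","contrast_M","contrast_S","pooled"
"red",0,0.0904451476350499,0,0.110772230708282,-0.110772230708282,0,0.0904451476350498
"red-blue",0,0.077233534371114,0.261203168827943,0.0945913751204678,-0.0945913751204678,0.452417159507988,0.272382294279956
"blue",0,1.26035310471548e-16,0.501934284815175,1.54361100114275e-16,-1.54361100114275e-16,0.869375683360631,0.501934284815175
"green-blue",0,-0.077233534371114,0.261203168827943,-0.0945913751204678,0.0945913751204678,0.452417159507988,0.272382294279956
"green",0,-0.0904451476350499,6.1469221528122e-17,-0.110772230708282,0.110772230708282,1.06467814788414e-16,0.0904451476350498
"green-yellow",0,-0.077233534371114,-0.261203168827942,-0.0945913751204678,0.0945913751204678,-0.452417159507987,0.272382294279956
"yellow",0,-2.5760878897058e-16,-0.501934284815175,-3.15505043117116e-16,3.15505043117116e-16,-0.869375683360631,0.501934284815175
"red-yellow",0,0.077233534371114,-0.261203168827943,0.0945913751204678,-0.0945913751204678,-0.452417159507988,0.272382294279956
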