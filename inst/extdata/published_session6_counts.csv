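domain,ot_crossed,ot_n,not_crossed,not_n
risk_suicidality,73,273,54,140
motivation,11,273,7,140
therapeutic_alliance,7,273,9,140
life_events,14,273,20,140
social_support,24,273,25,140
emotion_regulation,96,273,63,140
any_domain,145,273,104,140
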