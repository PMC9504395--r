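"topic","phrase"
"vaccine_type","pfizer"
"vaccine_type","moderna"
"vaccine_type","johnson amp johnson"
"vaccine_type","johnson johnson"
"vaccine_type","janssen"
"vaccine_type","biotech"
"phased_vaccination","frontline"
"phased_vaccination","phased"
"phased_vaccination","first dose"
"phased_vaccination","healthcare"
"phased_vaccination","old"
"phased_vaccination","second dose"
"phased_vaccination","operation"
"phased_vaccination","registration"
"phased_vaccination","cvs"
"phased_vaccination","pharmacy"
"phased_vaccination","administration"
"phased_vaccination","essential"
"phased_vaccination","medical condition"
"phased_vaccination","front line"
"phased_vaccination","health care"
"health_concern","side effect"
"health_concern","mask"
"health_concern","die"
"health_concern","warp speed"
"health_concern","warp"
"health_concern","fever"
"health_concern","tiredness"
"health_concern","headache"
"health_concern","muscle pain"
"health_concern","chills"
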