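sex,age_band,lesions_prevented,cost_million_eur
male,15-18,89638,6.64
male,19-24,152929,11.33
male,25-34,264635,19.61
male,35-50,376715,27.91
male,51-64,269952,20.00
male,65-80,165584,12.27
female,15-18,60061,4.45
female,19-24,109339,8.10
female,25-34,195755,14.51
female,35-50,279713,20.73
female,51-64,191175,16.95
female,65-80,132554,13.16
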