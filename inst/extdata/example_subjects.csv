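sex,smoker,stage
female,no,II
male,no,I
male,yes,III
female,yes,II
female,no,I
male,no,II
female,yes,I
male,yes,II
female,no,III
male,no,II
female,no,I
male,yes,III
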