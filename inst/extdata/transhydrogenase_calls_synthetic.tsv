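genome	membrane_transhydrogenase	soluble_transhydrogenase
A. aceti TMW2.1153	Yes	Yes
A. ascendens LMG 1590	Yes	No
A. ghanensis LMG 23848	Yes	No
A. oryzifermentans SLV-7	Yes	No
A. pasteurianus 386B	Yes	No
A. pasteurianus Ab3	No	Yes
A. persici TMW2.1084	Yes	No
A. pomorum BDGP5	Yes	No
A. senegalensis 108B	No	Yes
A. sp. JWB	Yes	No
A. tropicalis BDGP1	No	Yes
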