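red_parent: ZaosuRed
green_parent: KualaPear
original: Zaosu
red_pool: RedPool
green_pool: GreenPool
dominant_color: red
female_role: green_parent
male_role: red_parent
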