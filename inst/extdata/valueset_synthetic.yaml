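# SYNTHETIC Belgian-style EQ-5D-3L value set.
# These coefficients are invented for demonstration and testing: they mimic
# the structure of a published national tariff (constant decrement off full
# health, per-dimension level decrements, an any-level-3 indicator term,
# negative utilities possible for severe profiles) but are NOT a published
# value set. Transcribe real tariff coefficients into this format for
# production scoring.
name: synthetic-belgian-style-3L
constant: 0.152
decrements:
  mo: {l2: 0.074, l3: 0.285}
  sc: {l2: 0.083, l3: 0.260}
  ua: {l2: 0.033, l3: 0.100}
  pd: {l2: 0.057, l3: 0.226}
  ad: {l2: 0.080, l3: 0.208}
indicators:
  any_level_3: 0.256
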