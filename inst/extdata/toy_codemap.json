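{
  "pregnancy": ["PRG", "OBS"],
  "perinatal_congenital_lbw": ["LBW", "PER", "CNG"],
  "trauma_injury_poisoning": ["TRM", "INJ", "PSN", "FRC"],
  "mental_illness_addictions": ["MNT", "ADD", "PSY"],
  "acsc": ["ACS", "CHF", "CPD"],
  "cancer": ["CAN", "ONC", "NEO"]
}
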