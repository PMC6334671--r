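# Example housing-stock model for `acmscreen simulate --model ...`.
# All probability vectors must sum to 1. Materials without a
# presence_probs entry fall back to `default`.
period_probs:
  pre_1985: 0.50
  y1985_to_1990: 0.15
  post_1990: 0.25
  unknown: 0.10
presence_probs:
  default: {pre_1990: 0.95, post_1990: 0.95}
  fencing: {pre_1990: 0.60, post_1990: 0.35}
  outbuildings: {pre_1990: 0.40, post_1990: 0.25}
  heater_flues: {pre_1990: 0.30, post_1990: 0.10}
install_probs:
  pre_1990:
    original_pre_1990: 0.55
    replaced_post_1990: 0.15
    installed_post_1990: 0.05
    unknown: 0.25
  post_1990:
    original_pre_1990: 0.00
    replaced_post_1990: 0.10
    installed_post_1990: 0.70
    unknown: 0.20
visual_class_probs:
  non_acm: 0.40
  ambiguous: 0.35
  suggestive: 0.25
condition_probs:
  good: 0.40
  fair: 0.30
  poor: 0.20
  very_poor: 0.10
disturbance_probs:
  unlikely: 0.40
  somewhat_likely: 0.30
  likely: 0.20
  highly_likely: 0.10
seed: 1
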