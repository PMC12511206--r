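# Default dose coefficient scheme: ICRP publication 128 FDG coefficients
# and the whole-body DLP-to-effective-dose conversion factor.
# Assignment rule: a weight belongs to the entry with the largest
# lower_bound it exceeds (>= when lower_inclusive), so 45-65 kg (closed
# interval) maps to the 57 kg adult, > 65 kg to the 70 kg adult and
# < 45 kg to the 33 kg child.
dlp_conversion: 0.018
entries:
  - model_name: 33 kg child
    model_weight: 33
    coefficient: 0.036
    lower_bound: 0
    lower_inclusive: false
  - model_name: 57 kg adult
    model_weight: 57
    coefficient: 0.024
    lower_bound: 45
    lower_inclusive: true
  - model_name: 70 kg adult
    model_weight: 70
    coefficient: 0.019
    lower_bound: 65
    lower_inclusive: false
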