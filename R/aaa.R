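## Shared compartment constants (loaded before every other file).

ORGAN_NAMES <- c("lung", "liver", "gut", "kidney", "muscle", "adipose",
                 "skin", "brain", "heart", "bone", "spleen", "rest",
                 "arterial_blood", "venous_blood")

IDX <- setNames(seq_along(ORGAN_NAMES), ORGAN_NAMES)
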