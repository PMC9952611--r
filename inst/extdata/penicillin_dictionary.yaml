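# Standardized penicillin-class drugs with verbatim-name synonyms.
# Keys are the standardized names; synonyms are matched exactly after
# normalization (lowercase, whitespace collapse, dosage-token stripping).
# atc_class: J01CR combinations incl. beta-lactamase inhibitors;
# J01CA extended spectrum; J01CF beta-lactamase resistant;
# J01CE beta-lactamase sensitive.
piperacillin/tazobactam:
  atc_class: J01CR
  synonyms:
    - piperacillin-tazobactam
    - piperacillin and tazobactam
    - piperacillin sodium/tazobactam sodium
    - piperacillin w/tazobactam
    - zosyn
    - tazocin
    - piptaz
amoxicillin/clavulanic acid:
  atc_class: J01CR
  synonyms:
    - amoxicillin-clavulanic acid
    - amoxicillin/clavulanate
    - amoxicillin and clavulanate potassium
    - co-amoxiclav
    - augmentin
    - clavulin
ampicillin/sulbactam:
  atc_class: J01CR
  synonyms:
    - ampicillin-sulbactam
    - ampicillin and sulbactam
    - sultamicillin
    - unasyn
ampicillin:
  atc_class: J01CA
  synonyms:
    - ampicillin sodium
    - ampicillin trihydrate
    - principen
    - omnipen
amoxicillin:
  atc_class: J01CA
  synonyms:
    - amoxycillin
    - amoxicillin trihydrate
    - amoxil
    - trimox
piperacillin:
  atc_class: J01CA
  synonyms:
    - piperacillin sodium
    - pipracil
cloxacillin:
  atc_class: J01CF
  synonyms:
    - cloxacillin sodium
    - cloxapen
    - orbenin
flucloxacillin:
  atc_class: J01CF
  synonyms:
    - floxacillin
    - flucloxacillin sodium
    - floxapen
nafcillin:
  atc_class: J01CF
  synonyms:
    - nafcillin sodium
    - nallpen
    - unipen
oxacillin:
  atc_class: J01CF
  synonyms:
    - oxacillin sodium
    - bactocill
penicillin g:
  atc_class: J01CE
  synonyms:
    - benzylpenicillin
    - penicillin g potassium
    - penicillin g sodium
    - pfizerpen
penicillin v:
  atc_class: J01CE
  synonyms:
    - phenoxymethylpenicillin
    - penicillin v potassium
    - penicillin vk
    - pen-vee k
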