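# Illustrative cutoff configuration for sdqmix demonstrations and tests.
# These are NOT the published British (or any national) norm cutoff values;
# substantive analyses must supply their own file in this layout.
#
# Layout: informant -> scale -> boundaries [b1, b2] (+ optional direction).
# For high_worse scales b1/b2 are the upper bounds of the normal/borderline
# bands; for low_worse (strengths) scales they are the upper bounds of the
# abnormal/borderline bands. A score on a boundary falls in the band to its
# left (lower score side).
self:
  emotional:
    boundaries: [5, 6]
  conduct:
    boundaries: [3, 4]
  hyperactivity:
    boundaries: [5, 6]
  social:
    boundaries: [5, 6]
  prosocial:
    boundaries: [3, 4]
    direction: low_worse
  total_difficulties:
    boundaries: [15, 19]
parent:
  emotional:
    boundaries: [5, 6]
  conduct:
    boundaries: [3, 4]
  hyperactivity:
    boundaries: [5, 6]
  social:
    boundaries: [5, 6]
  prosocial:
    boundaries: [3, 4]
    direction: low_worse
  total_difficulties:
    boundaries: [15, 19]
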