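# PSA attribute registry: each attribute of the standard (sPSA) and extended
# (ePSA) Productivity Susceptibility Analysis, with the closed numeric
# interval of the underlying operating-model parameter for each ordinal risk
# score (1 = low risk, 2 = medium, 3 = high risk for both axes).
#
# Open-ended published categories are closed here so that every interval is
# finite and sampleable: SizeMaturity is capped at 450 cm (0.9 x the largest
# asymptotic length) and floored at 5 cm; RateIncrease at 2 /yr; VonBK domain
# is [0.02, 1.0] /yr; proportions are bounded by [0, 1].
#
# Selectivity is expressed relative to the length at 50% maturity
# (Lc / Lmat); Discard is a composite attribute carrying two sub-intervals
# (fraction of catch discarded, and fraction of discards dying).
attributes:
- name: AgeMaturity
  axis: productivity
  variants: [sPSA, ePSA]
  units: years
  ranges:
    '1': [1.0, 5.0]
    '2': [5.0, 15.0]
    '3': [15.0, 30.0]
- name: MaxAge
  axis: productivity
  variants: [sPSA, ePSA]
  units: years
  ranges:
    '1': [5.0, 10.0]
    '2': [10.0, 25.0]
    '3': [25.0, 60.0]
- name: MaxSize
  axis: productivity
  variants: [sPSA, ePSA]
  units: cm
  ranges:
    '1': [20.0, 100.0]
    '2': [100.0, 300.0]
    '3': [300.0, 500.0]
- name: SizeMaturity
  axis: productivity
  variants: [sPSA, ePSA]
  units: cm
  ranges:
    '1': [5.0, 40.0]
    '2': [40.0, 200.0]
    '3': [200.0, 450.0]
- name: Steepness
  axis: productivity
  variants: [sPSA, ePSA]
  units: dimensionless
  ranges:
    '1': [0.6, 0.95]
    '2': [0.4, 0.6]
    '3': [0.21, 0.4]
- name: RateIncrease
  axis: productivity
  variants: [ePSA]
  units: per year
  derived: true
  ranges:
    '1': [0.5, 2.0]
    '2': [0.16, 0.5]
    '3': [0.0, 0.16]
- name: VonBK
  axis: productivity
  variants: [ePSA]
  units: per year
  derived: true
  ranges:
    '1': [0.25, 1.0]
    '2': [0.15, 0.25]
    '3': [0.02, 0.15]
- name: Availability
  axis: susceptibility
  variants: [sPSA, ePSA]
  units: proportion of stock in fished area
  ranges:
    '1': [0.0, 0.25]
    '2': [0.25, 0.5]
    '3': [0.5, 1.0]
- name: Encounterability
  axis: susceptibility
  variants: [sPSA, ePSA]
  units: selectivity of the largest individuals
  ranges:
    '1': [0.0, 0.2]
    '2': [0.2, 0.8]
    '3': [0.8, 1.0]
- name: Selectivity
  axis: susceptibility
  variants: [sPSA, ePSA]
  units: Lc / Lmat
  ranges:           # score 1 is additionally capped at Lc <= 0.95 * Linf
    '1': [1.0, 10.0]
    '2': [0.5, 1.0]
    '3': [0.1, 0.5]
- name: Discard
  axis: susceptibility
  variants: [sPSA, ePSA]
  units: proportions
  composite: true
  ranges:            # fraction of the catch discarded
    '1': [0.5, 1.0]
    '2': [0.25, 0.75]
    '3': [0.0, 0.5]
  mortality_ranges:  # fraction of discards that die
    '1': [0.0, 0.25]
    '2': [0.25, 0.75]
    '3': [0.75, 1.0]
- name: Depletion
  axis: susceptibility
  variants: [ePSA]
  units: SSB / SSB0
  ranges:
    '1': [0.4, 0.8]
    '2': [0.25, 0.4]
    '3': [0.025, 0.25]
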