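# Heat vulnerability hierarchy, Spanish-style census (Logroño).
# The Health domain is designed with two indicators but the census publishes
# only one (collected: false marks the gap), so the domain is depleted and
# the Tier 2 halved-weight rule applies.
hazard: heat
city: Logrono
dimensions:
  - id: sensitivity
    label: Sensitivity
  - id: adaptive_capacity
    label: Adaptive Capacity
  - id: enhanced_exposure
    label: Enhanced Exposure
domains:
  - id: age
    label: Age
    dimension: sensitivity
  - id: health
    label: Health
    dimension: sensitivity
  - id: income
    label: Income
    dimension: adaptive_capacity
  - id: information_access
    label: Information Access/Use
    dimension: adaptive_capacity
  - id: local_knowledge
    label: Local Knowledge
    dimension: adaptive_capacity
  - id: tenure
    label: Tenure
    dimension: adaptive_capacity
  - id: social_network
    label: Social Network
    dimension: adaptive_capacity
  - id: housing_characteristics
    label: Housing Characteristics
    dimension: enhanced_exposure
  - id: physical_environment
    label: Physical Environment
    dimension: enhanced_exposure
indicators:
  - id: boys_under_5
    label: Boys under 5 years of age
    domain: age
    direction: vulnerability_increasing
    required: true
  - id: girls_under_5
    label: Girls under 5 years of age
    domain: age
    direction: vulnerability_increasing
    required: true
  - id: males_over_75
    label: Males over 75 years of age
    domain: age
    direction: vulnerability_increasing
    required: true
  - id: females_over_75
    label: Females over 75 years of age
    domain: age
    direction: vulnerability_increasing
    required: true
  - id: disability_preventing_work
    label: People with a disability preventing work
    domain: health
    direction: vulnerability_increasing
    required: true
  - id: persons_poor_health
    label: Persons with poor health
    domain: health
    direction: vulnerability_increasing
    required: true
    collected: false
  - id: one_parent_households
    label: One parent households
    domain: income
    direction: vulnerability_increasing
    required: true
    sub_ability: prepare
  - id: dependents_rate
    label: Dependents rate
    domain: income
    direction: vulnerability_increasing
    required: true
    sub_ability: recover
  - id: unemployment
    label: Unemployment
    domain: income
    direction: vulnerability_increasing
    required: true
    sub_ability: prepare
  - id: attending_university
    label: Population attending university
    domain: income
    direction: vulnerability_increasing
    required: true
    sub_ability: prepare
  - id: no_higher_education
    label: Population with no higher education
    domain: information_access
    direction: vulnerability_increasing
    required: true
    sub_ability: prepare
  - id: foreign_nationals
    label: Percentage of foreign nationals
    domain: local_knowledge
    direction: vulnerability_increasing
    required: true
    sub_ability: prepare
  - id: households_renting
    label: Households renting
    domain: tenure
    direction: vulnerability_increasing
    required: true
    sub_ability: prepare
  - id: one_person_households
    label: Households with one person
    domain: social_network
    direction: vulnerability_increasing
    required: true
    sub_ability: respond
  - id: primary_school_children
    label: Primary school age children
    domain: social_network
    direction: vulnerability_reducing
    required: true
    sub_ability: respond
  - id: pre1970_dwellings
    label: Dwellings constructed before 1970
    domain: housing_characteristics
    direction: vulnerability_increasing
    required: true
  - id: impervious_surface
    label: Impervious surface share
    domain: physical_environment
    direction: vulnerability_increasing
    required: true
  - id: tree_cover
    label: Tree cover share
    domain: physical_environment
    direction: vulnerability_reducing
    required: true
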