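# Flood vulnerability hierarchy, Irish-style census (Cork City).
# The ideal data situation: every domain carries its full designed set of
# indicators, every dimension holds at least two domains (Tier 1).
hazard: flood
city: Cork
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
  - id: mobility
    label: Mobility
    dimension: adaptive_capacity
  - id: physical_access
    label: Physical Access
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
  - id: children_under_5
    label: Children under 5 years of age
    domain: age
    direction: vulnerability_increasing
    required: true
  - id: adults_over_75
    label: Adults over 75 years of age
    domain: age
    direction: vulnerability_increasing
    required: true
  - id: persons_poor_health
    label: Persons with poor health
    domain: health
    direction: vulnerability_increasing
    required: true
  - id: disability_preventing_work
    label: People with a disability preventing work
    domain: health
    direction: vulnerability_increasing
    required: true
  - id: one_parent_households
    label: One parent households
    domain: income
    direction: vulnerability_increasing
    required: true
    sub_ability: prepare
  - id: children_per_family
    label: Children per family
    domain: income
    direction: vulnerability_increasing
    required: true
    sub_ability: prepare
  - id: low_skilled_employment
    label: Low skilled employment
    domain: income
    direction: vulnerability_increasing
    required: true
    sub_ability: prepare
  - id: employed_in_farming
    label: Population employed in farming
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
  - id: no_higher_education
    label: Population with no higher education
    domain: information_access
    direction: vulnerability_increasing
    required: true
    sub_ability: prepare
  - id: poor_english
    label: Population who do not speak English well or at all
    domain: information_access
    direction: vulnerability_increasing
    required: true
    sub_ability: respond
  - id: no_internet
    label: Households with no Internet
    domain: information_access
    direction: vulnerability_increasing
    required: true
    sub_ability: prepare
  - id: new_residents
    label: New residents
    domain: local_knowledge
    direction: vulnerability_increasing
    required: true
    sub_ability: prepare
  - id: foreign_nationals
    label: Foreign nationals
    domain: local_knowledge
    direction: vulnerability_increasing
    required: true
    sub_ability: prepare
  - id: no_motor_car
    label: Households with no motor car
    domain: mobility
    direction: vulnerability_increasing
    required: true
    sub_ability: respond
  - id: travel_time_to_work
    label: Travel time to work or school
    domain: physical_access
    direction: vulnerability_increasing
    required: true
    sub_ability: respond
  - id: households_renting
    label: Households renting
    domain: tenure
    direction: vulnerability_increasing
    required: true
    sub_ability: prepare
  - id: volunteering
    label: Volunteering
    domain: social_network
    direction: vulnerability_reducing
    required: true
    sub_ability: respond
  - id: primary_school_children
    label: Primary school age children
    domain: social_network
    direction: vulnerability_reducing
    required: true
    sub_ability: respond
  - id: one_person_households
    label: Households with one person
    domain: social_network
    direction: vulnerability_increasing
    required: true
    sub_ability: respond
  - id: no_central_heating
    label: Households with no central heating
    domain: housing_characteristics
    direction: vulnerability_increasing
    required: true
  - id: private_water_supply
    label: Households with private water supplies
    domain: housing_characteristics
    direction: vulnerability_increasing
    required: true
  - id: pre1945_dwellings
    label: Dwellings constructed before 1945
    domain: housing_characteristics
    direction: vulnerability_increasing
    required: true
  - id: caravan_mobile_homes
    label: Households that are caravans or mobile homes
    domain: housing_characteristics
    direction: vulnerability_increasing
    required: true
  - id: unoccupied_dwellings
    label: Unoccupied dwellings
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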