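# Attributes and levels of the tourist-partnership choice experiment.
# Level labels are the questionnaire wording. The money attribute carries
# per-level GMD values so it can be recoded as a single continuous column.
attributes:
  - name: condom_use
    units: ""
    coding: effects
    levels:
      - "Condom used every time"
      - "Condom used half of the time"
      - "Condom never used"
  - name: money
    units: "GMD"
    coding: effects
    numeric_values: [0, 500, 1000, 2000]
    levels:
      - "No money"
      - "500 dalasi"
      - "1000 dalasi"
      - "2000 dalasi"
  - name: when_money_given
    units: ""
    coding: effects
    levels:
      - "Immediately after sex"
      - "Money given at the end of your partner's trip"
      - "Money promised one week after partner leaves"
  - name: relationship_length
    units: ""
    coding: effects
    levels:
      - "One night"
      - "3-4 nights whilst partner is on holiday"
      - "Relationship lasts for their trip & partner will come back to see you in a few months"
      - "Relationship lasts for their trip & partner will invite you to Europe in a few months"
  - name: partner_age
    units: "years"
    coding: effects
    levels:
      - "30-40 years"
      - "40-50 years"
      - "50-60 years"
design:
  n_tasks: 8
  n_profile_alternatives: 2
  has_opt_out: true
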