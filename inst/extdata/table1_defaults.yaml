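age:
  base: 60.0
  low: 45.0
  high: 75.0
  dist: uniform
mortality:
  kind: gompertz
  h60: 0.0087
  h45: 0.0018
  high: 0.129
  max_age: 100.0
transitions:
  success:
    CCH:
      MCP:
        low:
          base: 0.61
          low: 0.52
          high: 0.71
          dist: beta
        high:
          base: 0.39
          low: 0.33
          high: 0.45
          dist: beta
      PIP:
        low:
          base: 0.33
          low: 0.28
          high: 0.38
          dist: beta
        high:
          base: 0.13
          low: 0.11
          high: 0.15
          dist: beta
    PNA:
      MCP:
        low:
          base: 0.58
          low: 0.49
          high: 0.67
          dist: beta
        high:
          base: 0.33
          low: 0.28
          high: 0.38
          dist: beta
      PIP:
        low:
          base: 0.37
          low: 0.31
          high: 0.43
          dist: beta
        high:
          base: 0.21
          low: 0.18
          high: 0.24
          dist: beta
    LF:
      MCP:
        low:
          base: 0.71
          low: 0.6
          high: 0.82
          dist: beta
        high:
          base: 0.61
          low: 0.52
          high: 0.7
          dist: beta
      PIP:
        low:
          base: 0.59
          low: 0.5
          high: 0.68
          dist: beta
        high:
          base: 0.25
          low: 0.21
          high: 0.29
          dist: beta
  recurrence:
    CCH:
      MCP:
        low:
          base: 0.25
          low: 0.21
          high: 0.29
          dist: beta
        high:
          base: 0.25
          low: 0.21
          high: 0.29
          dist: beta
      PIP:
        low:
          base: 0.48
          low: 0.41
          high: 0.55
          dist: beta
        high:
          base: 0.48
          low: 0.41
          high: 0.55
          dist: beta
    PNA:
      MCP:
        low:
          base: 0.26
          low: 0.22
          high: 0.3
          dist: beta
        high:
          base: 0.26
          low: 0.22
          high: 0.3
          dist: beta
      PIP:
        low:
          base: 0.4
          low: 0.34
          high: 0.46
          dist: beta
        high:
          base: 0.4
          low: 0.34
          high: 0.46
          dist: beta
    LF:
      MCP:
        low:
          base: 0.18
          low: 0.15
          high: 0.21
          dist: beta
        high:
          base: 0.18
          low: 0.15
          high: 0.21
          dist: beta
      PIP:
        low:
          base: 0.24
          low: 0.2
          high: 0.28
          dist: beta
        high:
          base: 0.24
          low: 0.2
          high: 0.28
          dist: beta
direct_costs:
  CCH:
    clinic_visit:
      base: 172.26
      low: 146.42
      high: 198.1
      dist: normal
    medication:
      base: 5400.0
      low: 4590.0
      high: 6210.0
      dist: normal
    manipulation_visit:
      base: 209.02
      low: 177.67
      high: 240.37
      dist: normal
    hand_therapy:
      base: 314.62
      low: 221.64
      high: 407.6
      dist: normal
  PNA:
    procedure:
      base: 322.91
      low: 274.47
      high: 371.35
      dist: normal
    hand_therapy:
      base: 673.57
      low: 487.61
      high: 859.53
      dist: normal
  LF:
    procedure:
      base: 1149.29
      low: 976.9
      high: 1321.68
      dist: normal
    anesthesia:
      base: 245.0
      low: 208.25
      high: 281.75
      dist: normal
    facility_fee:
      base: 2623.34
      low: 2229.84
      high: 3016.84
      dist: normal
    hand_therapy:
      base: 1394.35
      low: 1115.41
      high: 1859.25
      dist: normal
complication_costs:
  tendon_injury:
    base: 3479.56
    low: 2957.63
    high: 4001.49
    dist: normal
  admission:
    base: 7987.0
    low: 6788.95
    high: 9185.049999999999
    dist: normal
  medication_allergy:
    base: 176.23
    low: 149.8
    high: 202.66
    dist: normal
  skin_tear:
    base: 75.32
    low: 64.02
    high: 86.62
    dist: normal
  infection:
    base: 2746.26
    low: 2334.32
    high: 3158.2
    dist: normal
  crps:
    base: 2000.33
    low: 1700.28
    high: 2300.38
    dist: normal
  nerve_injury:
    base: 5435.18
    low: 4619.9
    high: 6250.46
    dist: normal
  artery_injury:
    base: 3581.64
    low: 3044.39
    high: 4118.89
    dist: normal
  hematoma:
    base: 1658.78
    low: 1409.96
    high: 1907.6
    dist: normal
complication_rates:
  CCH:
    tendon_injury:
      base: 0.0038
      low: 0.0034
      high: 0.0046
      dist: beta
    admission:
      base: 0.0156
      low: 0.0133
      high: 0.0179
      dist: beta
    medication_allergy:
      base: 0.0026
      low: 0.0022
      high: 0.003
      dist: beta
    skin_tear:
      base: 0.0397
      low: 0.0337
      high: 0.0457
      dist: beta
  PNA:
    tendon_injury:
      base: 0.0038
      low: 0.0032
      high: 0.0044
      dist: beta
    infection:
      base: 0.0155
      low: 0.0132
      high: 0.0178
      dist: beta
    crps:
      base: 0.0052
      low: 0.0044
      high: 0.006
      dist: beta
    nerve_injury:
      base: 0.0038
      low: 0.0032
      high: 0.0044
      dist: beta
    artery_injury:
      base: 0.0091
      low: 0.0077
      high: 0.0105
      dist: beta
  LF:
    tendon_injury:
      base: 0.0017
      low: 0.0014
      high: 0.002
      dist: beta
    admission:
      base: 0.0113
      low: 0.0096
      high: 0.013
      dist: beta
    infection:
      base: 0.0128
      low: 0.0109
      high: 0.0147
      dist: beta
    nerve_injury:
      base: 0.0216
      low: 0.0184
      high: 0.0248
      dist: beta
    artery_injury:
      base: 0.0095
      low: 0.0081
      high: 0.0109
      dist: beta
    hematoma:
      base: 0.0128
      low: 0.0109
      high: 0.0147
      dist: beta
days_off_work:
  CCH:
    base: 1.0
    low: 0.0
    high: 3.0
    dist: normal
  PNA:
    base: 1.0
    low: 0.0
    high: 14.0
    dist: normal
  LF:
    base: 37.0
    low: 14.0
    high: 60.0
    dist: normal
utilities:
  symptomatic:
    MCP:
      low:
        base: 0.969
        low: 0.824
        high: 1.0
        dist: beta
      high:
        base: 0.938
        low: 0.891
        high: 0.985
        dist: beta
    PIP:
      low:
        base: 0.97
        low: 0.922
        high: 1.0
        dist: beta
      high:
        base: 0.942
        low: 0.895
        high: 0.989
        dist: beta
  symptom_free: 1.0
economics:
  discount_rate: 0.03
  annual_income: 63179.0
  working_days: 365.0
  retirement_age: 65.0
  perspective: societal
  wtp: 100000.0
severity_threshold_deg: 45.0
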