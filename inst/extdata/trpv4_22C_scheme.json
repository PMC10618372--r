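{
  "states": ["C3", "C2", "C1", "O1", "O2", "O3"],
  "class_of_state": ["closed", "closed", "closed", "open", "open", "open"],
  "rates": [
    {
      "from": "C2",
      "to": "C3",
      "rate": 0.0551928852981015
    },
    {
      "from": "C3",
      "to": "C2",
      "rate": 0.0203127519446085
    },
    {
      "from": "C1",
      "to": "C2",
      "rate": 0.580057876912357
    },
    {
      "from": "C2",
      "to": "C1",
      "rate": 0.214010342846595
    },
    {
      "from": "O1",
      "to": "C1",
      "rate": 0.428333333312958
    },
    {
      "from": "C1",
      "to": "O1",
      "rate": 1.05871913825811
    },
    {
      "from": "O2",
      "to": "O1",
      "rate": 0.255611197930616
    },
    {
      "from": "O1",
      "to": "O2",
      "rate": 0.138916990885691
    },
    {
      "from": "O3",
      "to": "O2",
      "rate": 0.152225356906553
    },
    {
      "from": "O2",
      "to": "O3",
      "rate": 0.0415797875760015
    }
  ],
  "conductance_pS": 59.7,
  "vrev_mV": -18.89,
  "reference_temperature_C": 22,
  "forward": [
    {
      "from": "C3",
      "to": "C2"
    },
    {
      "from": "C2",
      "to": "C1"
    },
    {
      "from": "C1",
      "to": "O1"
    },
    {
      "from": "O1",
      "to": "O2"
    },
    {
      "from": "O2",
      "to": "O3"
    }
  ],
  "q10_forward": [
    1
  ]
}
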