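{
  "root": "ClinicalTrial",
  "templates": {
    "ClinicalTrial": [
      {
        "name": "AnalysesHealthCondition",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "CTDesign",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "CTduration",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "ConclusionComment",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "FinalNumberPatientsCT",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "NumberPatientsCT",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "ObjectiveDescription",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "hasArm",
        "kind": "template",
        "templates": ["Arm"],
        "min": 0,
        "max": null
      },
      {
        "name": "hasDiffBetweenGroups",
        "kind": "template",
        "templates": ["DiffBetweenGroups"],
        "min": 0,
        "max": null
      },
      {
        "name": "hasPopulation",
        "kind": "template",
        "templates": ["Population"],
        "min": 0,
        "max": null
      },
      {
        "name": "hasPublication",
        "kind": "template",
        "templates": ["Publication"],
        "min": 0,
        "max": null
      }
    ],
    "Arm": [
      {
        "name": "FinalNumPatientsArm",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "NumberAffected",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "NumberPatientsArm",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "PercentageAffected",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "hasIntervention",
        "kind": "template",
        "templates": ["Intervention"],
        "min": 0,
        "max": null
      },
      {
        "name": "hasOutcome",
        "kind": "template",
        "templates": ["Outcome"],
        "min": 0,
        "max": null
      }
    ],
    "Intervention": [
      {
        "name": "Frequency",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "RelativeFreqTime",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "hasMedication",
        "kind": "template",
        "templates": ["Medication"],
        "min": 0,
        "max": null
      }
    ],
    "Medication": [
      {
        "name": "DeliveryMethod",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "DoseUnit",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "DoseValue",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "Drug",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      }
    ],
    "Endpoint": [
      {
        "name": "AggregationMethod",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "BaselineUnit",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "EndoPointDescription",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "MeasurementDevice",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      }
    ],
    "Outcome": [
      {
        "name": "BaselineValue",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "ChangeValue",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "ObservedResult",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "PValueChangeValue",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "RelativeChangeValue",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "ResultMeasuredValue",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "SdDevBL",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "SdDevChangeValue",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "SdDevResValue",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "SdErrorChangeValue",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "TimePoint",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "hasEndpoint",
        "kind": "template",
        "templates": ["Endpoint"],
        "min": 0,
        "max": null
      }
    ],
    "DiffBetweenGroups": [
      {
        "name": "ConfIntervalDiff",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "DiffGroupAbsValue",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "PvalueDiff",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      }
    ],
    "Population": [
      {
        "name": "Country",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "Precondition",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      }
    ],
    "Publication": [
      {
        "name": "Author",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "Journal",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "PMID",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "PublicationYear",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      },
      {
        "name": "Title",
        "kind": "textual",
        "templates": [],
        "min": 0,
        "max": null
      }
    ]
  }
}
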