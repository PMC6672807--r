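{
  "form_id": "pneumonia_demo",
  "condition_label": "pneumonia",
  "sections": [
    {
      "section_kind": "true_false_I",
      "elements": [
        {
          "element_id": "pn_tf1_01",
          "label": "Fever",
          "element_kind": "true_false",
          "source_doc_type": "admission_record",
          "binding": {
            "concept_id": "SYN:MP001"
          }
        },
        {
          "element_id": "pn_tf1_02",
          "label": "Cough",
          "element_kind": "true_false",
          "source_doc_type": "admission_record",
          "binding": {
            "concept_id": "SYN:MP002"
          }
        },
        {
          "element_id": "pn_tf1_03",
          "label": "Poor appetite",
          "element_kind": "true_false",
          "source_doc_type": "admission_record",
          "binding": {
            "concept_id": "SYN:MP011"
          }
        },
        {
          "element_id": "pn_tf1_04",
          "label": "Vomiting",
          "element_kind": "true_false",
          "source_doc_type": "admission_record",
          "binding": {
            "concept_id": "SYN:MP012"
          }
        },
        {
          "element_id": "pn_tf1_05",
          "label": "Diarrhea",
          "element_kind": "true_false",
          "source_doc_type": "admission_record",
          "binding": {
            "concept_id": "SYN:MP013"
          }
        },
        {
          "element_id": "pn_tf1_06",
          "label": "Lethargy",
          "element_kind": "true_false",
          "source_doc_type": "admission_record",
          "binding": {
            "concept_id": "SYN:MP014"
          }
        },
        {
          "element_id": "pn_tf1_07",
          "label": "Rhinorrhea",
          "element_kind": "true_false",
          "source_doc_type": "admission_record",
          "binding": {
            "concept_id": "SYN:MP015"
          }
        },
        {
          "element_id": "pn_tf1_08",
          "label": "Sore throat",
          "element_kind": "true_false",
          "source_doc_type": "admission_record",
          "binding": {
            "concept_id": "SYN:MP016"
          }
        },
        {
          "element_id": "pn_tf1_09",
          "label": "Chest pain",
          "element_kind": "true_false",
          "source_doc_type": "admission_record",
          "binding": {
            "concept_id": "SYN:MP007"
          }
        },
        {
          "element_id": "pn_tf1_10",
          "label": "Wheezing",
          "element_kind": "true_false",
          "source_doc_type": "admission_record",
          "binding": {
            "concept_id": "SYN:MP010"
          }
        }
      ]
    },
    {
      "section_kind": "true_false_II",
      "elements": [
        {
          "element_id": "pn_tf2_01",
          "label": "Patchy infiltration",
          "element_kind": "true_false",
          "source_doc_type": "imaging_report",
          "binding": {
            "concept_id": "SYN:MP030"
          }
        },
        {
          "element_id": "pn_tf2_02",
          "label": "Lobar consolidation",
          "element_kind": "true_false",
          "source_doc_type": "imaging_report",
          "binding": {
            "concept_id": "SYN:MP031"
          }
        },
        {
          "element_id": "pn_tf2_03",
          "label": "Pleural effusion",
          "element_kind": "true_false",
          "source_doc_type": "imaging_report",
          "binding": {
            "concept_id": "SYN:MP032"
          }
        },
        {
          "element_id": "pn_tf2_04",
          "label": "Hilar lymphadenopathy",
          "element_kind": "true_false",
          "source_doc_type": "imaging_report",
          "binding": {
            "concept_id": "SYN:MP033"
          }
        },
        {
          "element_id": "pn_tf2_05",
          "label": "Atelectasis",
          "element_kind": "true_false",
          "source_doc_type": "imaging_report",
          "binding": {
            "concept_id": "SYN:MP034"
          }
        },
        {
          "element_id": "pn_tf2_06",
          "label": "Pneumothorax",
          "element_kind": "true_false",
          "source_doc_type": "imaging_report",
          "binding": {
            "concept_id": "SYN:MP035"
          }
        },
        {
          "element_id": "pn_tf2_07",
          "label": "Bronchial wall thickening",
          "element_kind": "true_false",
          "source_doc_type": "imaging_report",
          "binding": {
            "concept_id": "SYN:MP036"
          }
        },
        {
          "element_id": "pn_tf2_08",
          "label": "Increased lung markings",
          "element_kind": "true_false",
          "source_doc_type": "imaging_report",
          "binding": {
            "concept_id": "SYN:MP037"
          }
        },
        {
          "element_id": "pn_tf2_09",
          "label": "Cardiomegaly",
          "element_kind": "true_false",
          "source_doc_type": "imaging_report",
          "binding": {
            "concept_id": "SYN:MP038"
          }
        },
        {
          "element_id": "pn_tf2_10",
          "label": "Interstitial infiltration",
          "element_kind": "true_false",
          "source_doc_type": "imaging_report",
          "binding": {
            "concept_id": "SYN:MP039"
          }
        }
      ]
    },
    {
      "section_kind": "multiple_choice",
      "elements": [
        {
          "element_id": "pn_mc_01",
          "label": "Accompanying symptoms",
          "element_kind": "multiple_choice",
          "source_doc_type": "admission_record",
          "binding": {
            "options": [
              {
                "option_label": "hemoptysis",
                "concept_id": "SYN:MP045"
              },
              {
                "option_label": "night sweats",
                "concept_id": "SYN:MP046"
              },
              {
                "option_label": "chills",
                "concept_id": "SYN:MP047"
              }
            ]
          }
        },
        {
          "element_id": "pn_mc_02",
          "label": "Antimicrobial treatment",
          "element_kind": "multiple_choice",
          "source_doc_type": "admission_record",
          "binding": {
            "options": [
              {
                "option_label": "azithromycin",
                "concept_id": "SYN:TR004"
              },
              {
                "option_label": "amoxicillin",
                "concept_id": "SYN:TR005"
              },
              {
                "option_label": "oseltamivir",
                "concept_id": "SYN:TR006"
              }
            ]
          }
        },
        {
          "element_id": "pn_mc_03",
          "label": "Microbiological tests",
          "element_kind": "multiple_choice",
          "source_doc_type": "admission_record",
          "binding": {
            "options": [
              {
                "option_label": "sputum culture",
                "concept_id": "SYN:TE004"
              },
              {
                "option_label": "blood culture",
                "concept_id": "SYN:TE005"
              },
              {
                "option_label": "c reactive protein",
                "concept_id": "SYN:TE006"
              }
            ]
          }
        },
        {
          "element_id": "pn_mc_04",
          "label": "Relevant history",
          "element_kind": "multiple_choice",
          "source_doc_type": "admission_record",
          "binding": {
            "options": [
              {
                "option_label": "tuberculosis exposure",
                "concept_id": "SYN:MP048"
              },
              {
                "option_label": "influenza contact",
                "concept_id": "SYN:MP049"
              },
              {
                "option_label": "allergic rhinitis",
                "concept_id": "SYN:MP050"
              }
            ]
          }
        }
      ]
    }
  ]
}
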