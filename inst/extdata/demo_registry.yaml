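# Example drug registry for cohort assignment (see readDrugRegistry()).
drugs:
  - drug_id: blinatumomab
    class: TCE
    target: CD19
    share: 0.5
    synonyms: [BLINCYTO]
  - drug_id: talquetamab
    class: TCE
    target: GPRC5D
    share: 0.2
    synonyms: [TALVEY]
  - drug_id: tisagenlecleucel
    class: CART
    target: CD19
    share: 0.3
    synonyms: [KYMRIAH]
indication_keywords:
  - {group: Leukaemia, keyword: LEUKAEMIA}
  - {group: Leukaemia, keyword: LYMPHOBLASTIC}
  - {group: Lymphoma, keyword: LYMPHOMA}
  - {group: PlasmaCellNeoplasms, keyword: MYELOMA}
  - {group: SolidTumors, keyword: MELANOMA}
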