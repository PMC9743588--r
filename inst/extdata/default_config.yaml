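# Default pipeline configuration: relationship names for the derived model
# and the use-case refinements producing the final dashboard model (analysis
# subtype labels, material hierarchy merge, fusion/aneuploidy promotion into
# shared nodes, numeric measurement q as an analysis attribute).
name_map:
  ProjectPatient: InProject
  FamilyPatient: InFamily
  DiagnosisPatient: HasDiagnosis
  OrderPatient: HasOrder
  MaterialPatient: HasMaterial
  ResultAnalysis: HasResult
  Analysis.order_id: HasAnalysis
  Analysis.master_id: HasMaster
  Analysis.material_id: OnMaterial
  MaterialNumber.master_id: CreatedFrom
  DynamicField.analysis_id: HasDynamicField
refinements:
  - kind: absorb_entity
    absorbed: AnalysisMaster
    host: Analysis
    via: HasMaster
    mode: subtype_labels
  - kind: merge_hierarchy
    child: MaterialNumber
    parent: Material
    self_rel_name: CreatedFrom
  - kind: promote_field_entity
    key: fusion
    entity: Fusion
    rel: HasFusion
  - kind: promote_field_entity
    key: aneuploidy
    entity: Fusion
    rel: HasFusion
  - kind: promote_field_attribute
    key: q
analytics:
  reference_date: "2021-12-31"
  threshold: 0.2
  bin_width: 1
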