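# Relational schema of a pediatric-ALL diagnostics database: core entity
# relations plus the associative relations implementing the one-to-many and
# many-to-many links. The Patient-side FK is declared first in every
# associative relation; the stored direction of derived relationships follows
# FK declaration order.
relations:
  Patient:
    attributes: {id: integer, name: text, gender: text, dob: date}
    pk: [id]
  Project:
    attributes: {id: integer, name: text}
    pk: [id]
  Family:
    attributes: {id: integer, name: text}
    pk: [id]
  Order:
    attributes: {id: integer, type: text}
    pk: [id]
  Diagnosis:
    attributes: {id: integer, name: text, icd: text}
    pk: [id]
  DiagnosisAddition:
    attributes: {id: integer, description: text}
    pk: [id]
  AnalysisMaster:
    attributes: {id: integer, type: text}
    pk: [id]
  Analysis:
    attributes:
      id: integer
      order_id: integer
      master_id: integer
      material_id: integer
      result: text
    pk: [id]
    fks:
      - {columns: [order_id], ref_table: Order, ref_columns: [id]}
      - {columns: [master_id], ref_table: AnalysisMaster, ref_columns: [id]}
      - {columns: [material_id], ref_table: MaterialNumber, ref_columns: [id]}
  DynamicField:
    attributes: {analysis_id: integer, field: text, name: text, value: text}
    pk: [analysis_id, field]
    fks:
      - {columns: [analysis_id], ref_table: Analysis, ref_columns: [id]}
  Material:
    attributes: {id: integer, type: text}
    pk: [id]
  MaterialNumber:
    attributes:
      id: integer
      master_id: integer
      sub_type: text
      sub_number: integer
    pk: [id]
    fks:
      - {columns: [master_id], ref_table: Material, ref_columns: [id]}
  Result:
    attributes: {id: integer, description: text, value: text}
    pk: [id]
  ProjectPatient:
    attributes: {patient_id: integer, project_id: integer}
    pk: [patient_id, project_id]
    fks:
      - {columns: [patient_id], ref_table: Patient, ref_columns: [id]}
      - {columns: [project_id], ref_table: Project, ref_columns: [id]}
  FamilyPatient:
    attributes: {patient_id: integer, family_id: integer}
    pk: [patient_id, family_id]
    fks:
      - {columns: [patient_id], ref_table: Patient, ref_columns: [id]}
      - {columns: [family_id], ref_table: Family, ref_columns: [id]}
  DiagnosisPatient:
    attributes:
      patient_id: integer
      diagnosis_id: integer
      date: date
      addition: integer
    pk: [patient_id, diagnosis_id]
    fks:
      - {columns: [patient_id], ref_table: Patient, ref_columns: [id]}
      - {columns: [diagnosis_id], ref_table: Diagnosis, ref_columns: [id]}
      - {columns: [addition], ref_table: DiagnosisAddition, ref_columns: [id], optional: true}
  OrderPatient:
    attributes: {patient_id: integer, order_id: integer, order_date: date}
    pk: [patient_id, order_id]
    fks:
      - {columns: [patient_id], ref_table: Patient, ref_columns: [id]}
      - {columns: [order_id], ref_table: Order, ref_columns: [id]}
  MaterialPatient:
    attributes: {patient_id: integer, material_id: integer}
    pk: [patient_id, material_id]
    fks:
      - {columns: [patient_id], ref_table: Patient, ref_columns: [id]}
      - {columns: [material_id], ref_table: Material, ref_columns: [id]}
  ResultAnalysis:
    attributes: {analysis_id: integer, result_id: integer}
    pk: [analysis_id, result_id]
    fks:
      - {columns: [analysis_id], ref_table: Analysis, ref_columns: [id]}
      - {columns: [result_id], ref_table: Result, ref_columns: [id]}
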