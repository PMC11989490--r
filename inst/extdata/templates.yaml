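# Sentence templates for the synthetic discharge-report generator, keyed by
# language. Slots in {braces} are filled at render time. Filler sentences
# are chosen so that they never match any extraction pattern of the bundled
# schema inside their section.
es:
  header: "INFORME DE ALTA\nServicio de Cardiología\nFecha de alta: {date}\nPaciente: {patient_id}"
  headings:
    ReasonForConsultation: "MOTIVO DE CONSULTA:"
    PersonalHistory: "ANTECEDENTES PERSONALES:"
    CurrentIllness: "ENFERMEDAD ACTUAL:"
    GeneralExploration: "EXPLORACIÓN GENERAL:"
    ComplementaryTests: "PRUEBAS COMPLEMENTARIAS:"
    Diagnosis: "DIAGNÓSTICO:"
    Treatment: "TRATAMIENTO:"
    Evolution: "EVOLUCIÓN:"
  reason_demo:
    - "{sex} de {age} años que consulta por {complaint}."
    - "{sex} de {age} años derivado a urgencias por {complaint}."
  reason_plain:
    - "Consulta por {complaint}."
    - "Acude a urgencias por {complaint}."
  complaints: ["palpitaciones", "disnea", "dolor torácico", "mareo", "síncope", "astenia"]
  sex_surfaces:
    male: ["Varón", "Hombre"]
    female: ["Mujer"]
  history_affirmed:
    - "{surface}."
    - "Diagnosticado de {surface}."
    - "En tratamiento por {surface}."
    - "{surface} de larga evolución."
  history_negated:
    - "No refiere {surface}."
    - "Sin {surface}."
    - "Niega {surface}."
  lab:
    - "{surface}: {value} {unit}."
    - "{surface} {value} {unit}."
  echo:
    - "Ecocardiograma: {surface} {value} {unit}."
    - "{surface} {value} {unit}."
  medication:
    - "Se inicia {surface}."
    - "Se pauta {surface} al alta."
    - "Continúa tratamiento con {surface}."
  procedure_affirmed:
    - "Se realiza {surface}."
    - "{surface} programada durante el ingreso."
  procedure_negated:
    - "No se realiza {surface}."
  af_onset_qualified:
    - "Fibrilación auricular de novo."
    - "Primer episodio de fibrilación auricular."
    - "Fibrilación auricular de nueva aparición."
  af_onset_bare:
    - "Fibrilación auricular con respuesta ventricular rápida."
    - "Fibrilación auricular paroxística."
  af_onset_current_illness:
    - "Durante el ingreso se objetiva fibrilación auricular de novo."
    - "Debut de fibrilación auricular durante el ingreso."
  af_prior:
    - "Fibrilación auricular paroxística conocida."
    - "FA permanente en tratamiento anticoagulante."
    - "Historia de fibrilación auricular."
  af_negated:
    - "Se descarta fibrilación auricular."
    - "No se objetiva fibrilación auricular en la monitorización."
  distractor_lab:
    - "Control ambulatorio con {surface} {value} {unit}."
    - "Pendiente control de {surface} en consultas."
  filler:
    CurrentIllness:
      - "Refiere clínica de varias horas de evolución."
      - "Cuadro progresivo en los últimos días."
    GeneralExploration:
      - "Auscultación cardíaca rítmica, sin soplos."
      - "Afebril, eupneico en reposo."
      - "Tensión arterial dentro de la normalidad."
    Evolution:
      - "Buena evolución clínica durante el ingreso."
      - "El paciente permanece estable al alta."
      - "Ingreso sin complicaciones."
    Diagnosis:
      - "Sin otros hallazgos relevantes."
    Treatment:
      - "Se recomienda control por su médico de atención primaria."
      - "Dieta baja en sal."
    PersonalHistory:
      - "Sin otros antecedentes de interés."
en:
  header: "DISCHARGE REPORT\nCardiology Department\nDischarge date: {date}\nPatient: {patient_id}"
  headings:
    ReasonForConsultation: "REASON FOR CONSULTATION:"
    PersonalHistory: "PERSONAL HISTORY:"
    CurrentIllness: "CURRENT ILLNESS:"
    GeneralExploration: "GENERAL EXPLORATION:"
    ComplementaryTests: "COMPLEMENTARY TESTS:"
    Diagnosis: "DIAGNOSIS:"
    Treatment: "TREATMENT:"
    Evolution: "EVOLUTION:"
  reason_demo:
    - "{age}-year-old {sex} presenting with {complaint}."
    - "{age}-year-old {sex} referred for {complaint}."
  reason_plain:
    - "Presenting with {complaint}."
    - "Admitted for {complaint}."
  complaints: ["palpitations", "dyspnea", "chest pain", "dizziness", "syncope", "fatigue"]
  sex_surfaces:
    male: ["man", "male"]
    female: ["woman", "female"]
  history_affirmed:
    - "{surface}."
    - "Diagnosed with {surface}."
    - "Under treatment for {surface}."
    - "Long-standing {surface}."
  history_negated:
    - "Denies {surface}."
    - "No {surface}."
    - "Without {surface}."
  lab:
    - "{surface}: {value} {unit}."
    - "{surface} {value} {unit}."
  echo:
    - "Echocardiogram: {surface} {value} {unit}."
    - "{surface} {value} {unit}."
  medication:
    - "Started on {surface}."
    - "{surface} prescribed at discharge."
    - "Continues treatment with {surface}."
  procedure_affirmed:
    - "{surface} was performed."
    - "{surface} scheduled during admission."
  procedure_negated:
    - "No {surface} was performed."
  af_onset_qualified:
    - "New-onset atrial fibrillation."
    - "First episode of atrial fibrillation."
    - "De novo atrial fibrillation."
  af_onset_bare:
    - "Atrial fibrillation with rapid ventricular response."
    - "Paroxysmal atrial fibrillation."
  af_onset_current_illness:
    - "New-onset atrial fibrillation documented during admission."
    - "Atrial fibrillation debut during admission."
  af_prior:
    - "Known paroxysmal atrial fibrillation."
    - "Permanent AF on anticoagulation."
    - "History of atrial fibrillation."
  af_negated:
    - "Atrial fibrillation ruled out."
    - "No atrial fibrillation on monitoring."
  distractor_lab:
    - "Outpatient follow-up showed {surface} {value} {unit}."
    - "Repeat {surface} pending at follow-up."
  filler:
    CurrentIllness:
      - "Symptoms of several hours of evolution."
      - "Progressive course over the last days."
    GeneralExploration:
      - "Regular heart sounds, no murmurs."
      - "Afebrile, comfortable at rest."
      - "Blood pressure within normal range."
    Evolution:
      - "Good clinical course during admission."
      - "The patient remained stable at discharge."
      - "Uneventful admission."
    Diagnosis:
      - "No other relevant findings."
    Treatment:
      - "Follow-up with primary care physician recommended."
      - "Low-salt diet."
    PersonalHistory:
      - "No other relevant background."
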