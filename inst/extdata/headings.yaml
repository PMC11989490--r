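# Heading lexicons for the section segmenter, keyed by language.
# Surface forms are matched case-insensitively after accent folding and
# stripping of one trailing colon; a heading must occupy a whole line.
es:
  Header: ["informe de alta", "informe clinico de alta", "informe de alta hospitalaria"]
  ReasonForConsultation: ["motivo de consulta", "motivo de ingreso"]
  PersonalHistory: ["antecedentes personales", "antecedentes"]
  CurrentIllness: ["enfermedad actual", "historia actual"]
  GeneralExploration: ["exploracion general", "exploracion fisica"]
  ComplementaryTests: ["pruebas complementarias", "exploraciones complementarias"]
  Diagnosis: ["diagnostico", "diagnosticos", "juicio clinico", "juicio diagnostico"]
  Treatment: ["tratamiento", "tratamiento al alta", "plan de tratamiento"]
  Evolution: ["evolucion", "evolucion y comentarios"]
en:
  Header: ["discharge report", "discharge summary"]
  ReasonForConsultation: ["reason for consultation", "chief complaint"]
  PersonalHistory: ["personal history", "past medical history"]
  CurrentIllness: ["current illness", "history of present illness"]
  GeneralExploration: ["general exploration", "physical examination"]
  ComplementaryTests: ["complementary tests", "diagnostic tests"]
  Diagnosis: ["diagnosis", "diagnoses", "clinical impression"]
  Treatment: ["treatment", "discharge treatment", "treatment plan"]
  Evolution: ["evolution", "clinical course"]
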