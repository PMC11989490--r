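# NegEx-style negation rule sets, keyed by language. Phrases are stored
# lower-cased and accent-folded; multi-word triggers are matched as
# consecutive token sequences.
es:
  pre_triggers: ["no", "sin", "niega", "no refiere", "se descarta", "descarta",
                 "ausencia de", "no se objetiva", "no se evidencia"]
  post_triggers: ["descartada", "descartado", "negativo", "negativa", "ausente"]
  terminators: ["pero", "aunque", "salvo", "excepto", ",", ";", ".", ":"]
  scope_window: 5
en:
  pre_triggers: ["no", "not", "without", "denies", "denied", "ruled out",
                 "rules out", "absence of", "negative for", "free of"]
  post_triggers: ["ruled out", "excluded", "absent", "negative", "unlikely"]
  terminators: ["but", "although", "except", "however", ",", ";", ".", ":"]
  scope_window: 5
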