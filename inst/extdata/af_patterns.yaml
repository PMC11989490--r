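# Atrial-fibrillation mention patterns, keyed by language. Regexes are
# applied to lower-cased, accent-folded text. "onset" patterns are
# onset-qualified phrasings (first documented episode); "bare" patterns are
# unqualified AF mentions.
es:
  bare:
    - "fibrilacion auricular"
    - "\\bfa\\b"
  onset:
    - "fibrilacion auricular de novo"
    - "primer episodio de fibrilacion auricular"
    - "debut de fibrilacion auricular"
    - "fibrilacion auricular de nueva aparicion"
    - "fa de novo"
en:
  bare:
    - "atrial fibrillation"
    - "\\bafib\\b"
    - "\\baf\\b"
  onset:
    - "new[- ]onset atrial fibrillation"
    - "first episode of atrial fibrillation"
    - "de novo atrial fibrillation"
    - "atrial fibrillation debut"
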