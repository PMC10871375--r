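# NegEx-style negation triggers. Pre-cues negate a mention within `window`
# tokens before it; post-cues within the window after. Scope is cut by the
# terminator conjunctions and by sentence boundaries.
window: 5
# "no"/"yes" must stay quoted: bare YAML would read them as booleans
pre: ["no", "not", "denies", "denied", "without", "negative for",
      "absence of", "free of"]
post: ["unlikely", "was ruled out", "is ruled out", "ruled out"]
terminators: ["but", "however", "although", "yet", "except", "aside"]
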