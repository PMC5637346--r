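# Gradable-qualifier lexicon for DEG statement extraction.
# Matching is case-insensitive; when several phrases match a sentence the
# longest match wins. Edit freely: the five phrase classes must stay
# pairwise disjoint.
increase_phrases:
  - elevated
  - increased
  - overexpressed
  - overexpression
  - over-expressed
  - upregulated
  - up-regulated
  - upregulation
  - significantly overexpressed
  - significantly elevated
  - significantly increased
  - higher expression
  - increased expression
  - enhanced expression
high_increase_phrases:
  - greatly elevated
  - greatly increased
  - markedly increased
  - markedly elevated
  - strongly overexpressed
  - strongly upregulated
  - highly overexpressed
  - highly elevated
  - dramatically increased
decrease_phrases:
  - decreased
  - reduced
  - downregulated
  - down-regulated
  - downregulation
  - underexpressed
  - under-expressed
  - decreased expression
  - significantly decreased
  - significantly reduced
  - lower expression
  - reduced expression
  - diminished expression
high_decrease_phrases:
  - greatly decreased
  - greatly reduced
  - markedly decreased
  - markedly reduced
  - strongly downregulated
  - highly reduced
  - dramatically decreased
  - nearly absent
excluded_phrases:
  - altered
  - alteration
  - aberrant
  - abnormal
  - dysregulation
  - dysregulated
  - expressed differentially
  - differentially expressed
  - modulated
  - discordant
trigger_substrings:
  - express
  - production
  - produce
  - transcription
  - transcribe
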