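# Example user lexicon configuration (same shape as any production lexicon).
# This demonstration list is NOT a clinically validated instrument.
name: demo-youth-lexicon-file
version: "0.1"
keywords:
  - suicide
  - suicidal
  - selfharm
  - overdose
  - unalive
slang_terms:
  - kms
  - kys
  - sewerslide
  - oding
  - unaliving
multiword_phrases:
  - end it all
  - no reason to live
  - want to disappear forever
emoji_set:
  - "☠"
  - "🪦"
  - "🗡"
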