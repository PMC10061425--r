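# Synthetic starter fixture of organisms common on human skin and in oral
# and nasal cavities, possible sources of human-derived contamination.
# Placeholder source labels; fixture only, not a curated panel.
name: human-related
entries:
  Staphylococcus: {rank: genus, sources: [skin-panel]}
  Cutibacterium: {rank: genus, sources: [skin-panel]}
  Corynebacterium: {rank: genus, sources: [skin-panel, nasal-panel]}
  Streptococcus: {rank: genus, sources: [oral-panel]}
  Prevotella: {rank: genus, sources: [oral-panel]}
  Veillonella: {rank: genus, sources: [oral-panel]}
  Neisseria: {rank: genus, sources: [oral-panel, nasal-panel]}
  Haemophilus: {rank: genus, sources: [nasal-panel]}
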