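# Synthetic starter fixture of recurrently reported contaminant taxa.
# It mirrors the top-8 most reported genera and species of the curated
# literature list (with their per-taxon source counts) but uses placeholder
# source labels: it is a small fixture of the dynamically maintained
# community list, NOT a reproduction of the full curation.
name: contaminants
entries:
  Pseudomonas:
    rank: genus
    sources: [study-01, study-02, study-03, study-04, study-05, study-06,
              study-07, study-08, study-09, study-10, study-11, study-12,
              study-13]
  Stenotrophomonas:
    rank: genus
    sources: [study-01, study-02, study-03, study-04, study-05, study-06,
              study-07, study-08, study-09, study-10, study-11, study-12,
              study-13]
  Ralstonia:
    rank: genus
    sources: [study-01, study-02, study-03, study-04, study-05, study-06,
              study-07, study-08, study-09, study-10, study-11, study-12]
  Bradyrhizobium:
    rank: genus
    sources: [study-01, study-02, study-03, study-04, study-05, study-06,
              study-07, study-08, study-09, study-10, study-11]
  Methylobacterium:
    rank: genus
    sources: [study-01, study-02, study-03, study-04, study-05, study-06,
              study-07, study-08, study-09, study-10, study-11]
  Acinetobacter:
    rank: genus
    sources: [study-01, study-02, study-03, study-04, study-05, study-06,
              study-07, study-08, study-09, study-10]
  Corynebacterium:
    rank: genus
    sources: [study-01, study-02, study-03, study-04, study-05, study-06,
              study-07, study-08, study-09, study-10]
  Sphingomonas:
    rank: genus
    sources: [study-01, study-02, study-03, study-04, study-05, study-06,
              study-07, study-08, study-09, study-10]
  Cutibacterium acnes:
    rank: species
    sources: [study-01, study-02, study-03, study-04]
  Pseudomonas fluorescens:
    rank: species
    sources: [study-01, study-02, study-03, study-04]
  Stenotrophomonas maltophilia:
    rank: species
    sources: [study-01, study-02, study-03, study-04]
  Acinetobacter baumannii:
    rank: species
    sources: [study-01, study-02, study-03]
  Bradyrhizobium elkanii:
    rank: species
    sources: [study-01, study-02, study-03]
  Corynebacterium tuberculostearicum:
    rank: species
    sources: [study-01, study-02, study-03]
  Rhodococcus fascians:
    rank: species
    sources: [study-01, study-02, study-03]
  Streptococcus mitis:
    rank: species
    sources: [study-01, study-02, study-03]
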