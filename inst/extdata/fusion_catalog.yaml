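# Canonical fusion and aneuploidy names with alias spellings observed in
# diagnostic records, plus carrier prevalences used as synthetic-cohort
# defaults. Aneuploidies live in the same namespace as fusions (tokens
# ANEUPLOIDY:<TYPE>) so they share node identity and feature encoding.
# Prevalences are generator defaults in the plausible range for pediatric
# B-ALL subgroups; they are scale parameters, not clinical claims.
fusions:
  ETV6-RUNX1:
    aliases: [TEL-AML1, "t(12;21)", ETV6/RUNX1]
    prevalence: 0.22
  CRLF2-P2RY8:
    aliases: [P2RY8-CRLF2, CRLF2/P2RY8]
    prevalence: 0.08
  BCR-ABL1:
    aliases: [BCR-ABL, "t(9;22)", Philadelphia chromosome]
    prevalence: 0.03
  TCF3-PBX1:
    aliases: [E2A-PBX1, "t(1;19)"]
    prevalence: 0.05
  KMT2A-AFF1:
    aliases: [MLL-AF4, "t(4;11)"]
    prevalence: 0.02
  PAX5:
    aliases: [PAX5alt, PAX5 fusion]
    prevalence: 0.07
  "ANEUPLOIDY:HYPERDIPLOIDY":
    aliases: [Hyperdiploidy, High hyperdiploidy, HeH]
    prevalence: 0.25
  "ANEUPLOIDY:HYPODIPLOIDY":
    aliases: [Hypodiploidy, Low hypodiploidy]
    prevalence: 0.02
  "ANEUPLOIDY:IAMP21":
    aliases: [iAMP21, "intrachromosomal amplification of chromosome 21"]
    prevalence: 0.02
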