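{
  "description": "Synthetic codon-level evidence-tier map for p53 (NP_000537.3). The published assay interpretation consulted VCEP missense classifications, functional-assay datasets and bioinformatic predictors that are not redistributed here; these intervals were reverse-engineered so that the strongest-tier-overlapping rule reproduces every in-frame PVS1 (RNA) weight reported by the assay. They are curated data, not code, and can be replaced by a user-supplied map.",
  "tiers": [
    {"codon_start": 33,  "codon_end": 68,  "tier": "PATHOGENIC_MISSENSE",    "source_note": "exon 4 amino-terminal region deleted by events assigned full PVS1"},
    {"codon_start": 69,  "codon_end": 125, "tier": "FUNCTIONAL_DAMAGING",    "source_note": "exon 4 region with damaging functional-assay evidence only (PVS1_Strong events)"},
    {"codon_start": 126, "codon_end": 183, "tier": "PATHOGENIC_MISSENSE",    "source_note": "exon 5 acceptor-side region deleted by events assigned full PVS1"},
    {"codon_start": 184, "codon_end": 187, "tier": "BIOINFORMATIC_DAMAGING", "source_note": "exon 5 donor-side codons with bioinformatic-only damaging predictions (PVS1_Supporting)"},
    {"codon_start": 249, "codon_end": 260, "tier": "PATHOGENIC_MISSENSE",    "source_note": "exon 7 donor-side region incl. Arg249 hotspot"},
    {"codon_start": 261, "codon_end": 262, "tier": "BENIGN_PREDICTED",       "source_note": "Ser261/Gly262 junction; single-residue insertion predicted benign"},
    {"codon_start": 263, "codon_end": 269, "tier": "FUNCTIONAL_DAMAGING",    "source_note": "exon 8 proximal acceptor-side region; damaging in functional assays"},
    {"codon_start": 270, "codon_end": 279, "tier": "PATHOGENIC_MISSENSE",    "source_note": "exon 8 acceptor-side region incl. Arg273 hotspot"},
    {"codon_start": 293, "codon_end": 306, "tier": "FUNCTIONAL_DAMAGING",    "source_note": "exon 8 donor-side region with functional-assay evidence only"},
    {"codon_start": 307, "codon_end": 308, "tier": "BENIGN_PREDICTED",       "source_note": "Ala307/Leu308 junction; single amino-acid deletions predicted benign by BayesDel"}
  ]
}
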