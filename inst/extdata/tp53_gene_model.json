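{
  "transcript": "NM_000546.6",
  "protein": "NP_000537.3",
  "full_length_size_nt": 1202,
  "exons": [
    {"exon_id": 2, "cdna_start": 1, "cdna_end": 74},
    {"exon_id": 3, "cdna_start": 75, "cdna_end": 96},
    {"exon_id": 4, "cdna_start": 97, "cdna_end": 375},
    {"exon_id": 5, "cdna_start": 376, "cdna_end": 559},
    {"exon_id": 6, "cdna_start": 560, "cdna_end": 672},
    {"exon_id": 7, "cdna_start": 673, "cdna_end": 782},
    {"exon_id": 8, "cdna_start": 783, "cdna_end": 919},
    {"exon_id": 9, "cdna_start": 920, "cdna_end": 993}
  ],
  "introns": [
    {"intron_id": "2", "length_nt": null, "contains_in_frame_stop": null},
    {"intron_id": "3", "length_nt": null, "contains_in_frame_stop": null},
    {"intron_id": "4", "length_nt": null, "contains_in_frame_stop": null},
    {"intron_id": "5", "length_nt": null, "contains_in_frame_stop": true},
    {"intron_id": "6", "length_nt": null, "contains_in_frame_stop": true},
    {"intron_id": "7", "length_nt": null, "contains_in_frame_stop": true},
    {"intron_id": "8", "length_nt": null, "contains_in_frame_stop": null},
    {"intron_id": "9-mg", "length_nt": null, "contains_in_frame_stop": true,
     "note": "minigene vector context downstream of exon 9; retention characterised as PTC in the assay"}
  ],
  "protein_length": 393,
  "protein_residues": "MEEPQSDPSVEPPLSQETFSDLWKLLPENNVLSPLPSQAMDDLMLSPDDIEQWFTEDPGPDEAPRMPEAAPPVAPAPAAPTPAAPAPAPSWPLSSSVPSQKTYQGSYGFRLGFLHSGTAKSVTCTYSPALNKMFCQLAKTCPVQLWVDSTPPPGTRVRAMAIYKQSQHMTEVVRRCPHHERCSDSDGLAPPQHLIRVEGNLRVEYLDDRNTFRHSVVVPYEPPEVGSDCTTIHYNYMCNSSCMGGMNRRPILTIITLEDSSGNLLGRNSFEVRVCACPGRDRRTEEENLRKKGEPHHELPPGSTKRALPNNTSSSPQPKKKPLDGEYFTLQIRGRERFEMFRELNEALELKDAQAGKEPGGSRAHSSHLKSKKGQSTSRHKKLMFKTEGPDSD",
  "junction_notation": {
    "▼(E8p3)": "p.Ser261_Gly262insSer",
    "Δ(E9p3)": "p.Ala307_Leu308delinsVal"
  },
  "junction_notation_note": "Replacement/inserted residues of boundary-merging in-frame events are not derivable from codon arithmetic alone; these two entries are annotations carried over from the assay characterisation of the products."
}
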