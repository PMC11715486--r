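#' Gene model for the TP53 exon 2-9 minigene
#'
#' A gene model holds the coding-exon layout of the minigene insert in
#' 1-based inclusive cDNA (coding) coordinates, the minigene intron
#' annotations, the expected full-length RT-PCR product size, and optional
#' protein-level annotation used when naming in-frame consequences.
#'
#' @param path Path to a gene-model JSON config.
#' @return An object of class `gene_model`.
#' @export
load_gene_model <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  exons <- as.data.frame(cfg$exons)
  introns <- as.data.frame(cfg$introns)
  introns$intron_id <- as.character(introns$intron_id)
  jn <- cfg$junction_notation
  model <- structure(
    list(
      transcript = cfg$transcript %||% NA_character_,
      exons = exons[order(exons$exon_id), , drop = FALSE],
      introns = introns,
      full_length_size_nt = as.integer(cfg$full_length_size_nt),
      protein_length = if (is.null(cfg$protein_length)) NA_integer_ else as.integer(cfg$protein_length),
      protein_residues = cfg$protein_residues %||% NA_character_,
      junction_notation = if (is.null(jn)) list() else as.list(jn)
    ),
    class = "gene_model"
  )
  validate_gene_model(model)
  model
}

#' @export
print.gene_model <- function(x, ...) {
  cat("Gene model:", x$transcript, "\n")
  cat(sprintf("  %d exons (cDNA %d..%d), full-length product %d nt\n",
              nrow(x$exons), min(x$exons$cdna_start), max(x$exons$cdna_end),
              x$full_length_size_nt))
  cat("  introns:", paste(x$introns$intron_id, collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_gene_model <- function(model) {
  ex <- model$exons
  if (nrow(ex) == 0L) stop("gene model has no exons")
  if (any(ex$cdna_end < ex$cdna_start)) stop("exon with end < start")
  if (is.unsorted(ex$cdna_start)) stop("exons not sorted by cDNA start")
  if (any(diff(ex$exon_id) != 1L)) stop("exon numbering not contiguous")
  # coding coordinates are contiguous: each exon starts where the previous ended + 1
  if (nrow(ex) > 1L && any(ex$cdna_start[-1] != ex$cdna_end[-nrow(ex)] + 1L))
    stop("exon cDNA ranges overlap or leave gaps")
  invisible(model)
}

#' Shipped TP53 NM_000546.6 minigene gene model
#'
#' Coding-exon boundaries follow the RefSeq NM_000546.6 annotation for
#' exons 2-9 (the exons carried by the minigene insert); intron lengths
#' within the construct are not published, so intron entries carry only a
#' `contains_in_frame_stop` annotation for the introns whose full retention
#' the assay characterised.
#'
#' @return A `gene_model`.
#' @export
tp53_gene_model <- function() {
  load_gene_model(system.file("extdata", "tp53_gene_model.json",
                              package = "tp53splice", mustWork = TRUE))
}

exon_row <- function(model, exon_id) {
  i <- match(exon_id, model$exons$exon_id)
  if (is.na(i)) stop(sprintf("exon %s not in gene model", exon_id))
  model$exons[i, ]
}

intron_row <- function(model, intron_id) {
  i <- match(as.character(intron_id), model$introns$intron_id)
  if (is.na(i)) stop(sprintf("intron %s not in gene model", intron_id))
  model$introns[i, ]
}

exon_length <- function(model, exon_id) {
  e <- exon_row(model, exon_id)
  e$cdna_end - e$cdna_start + 1L
}

# intron immediately downstream of an exon (minigene vector context after
# the last exon gets its own id, e.g. "9-mg")
downstream_intron_id <- function(model, exon_id) {
  cand <- c(as.character(exon_id), paste0(exon_id, "-mg"))
  hit <- cand[cand %in% model$introns$intron_id]
  if (length(hit) == 0L) stop(sprintf("no intron downstream of exon %s in model", exon_id))
  hit[[1L]]
}

upstream_intron_id <- function(model, exon_id) {
  downstream_intron_id(model, as.integer(exon_id) - 1L)
}

codon_of <- function(cdna_pos) as.integer(floor((cdna_pos - 1) / 3) + 1)

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val")

residue3 <- function(model, codon) {
  if (is.na(model$protein_residues)) return("Xaa")
  if (codon < 1L || codon > nchar(model$protein_residues)) return("Xaa")
  aa1 <- substr(model$protein_residues, codon, codon)
  out <- unname(AA3[aa1])
  if (length(out) != 1L || is.na(out)) "Xaa" else out
}
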