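#' Gene model container
#'
#' A set of gene models: strand-aware transcript coordinates plus ordered
#' exon intervals. All coordinates are 0-based half-open `[start, end)`;
#' strand affects only the transcription-order labels (first/last exon,
#' TSS/TES), never interval arithmetic. On the minus strand the TSS is the
#' larger genomic coordinate and exon index 1 (first transcribed exon) is
#' the rightmost genomic exon.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `tx_start`, `tx_end` (genomic span, `tx_start < tx_end`).
#' @param exons data.frame with columns `gene_id`, `exon_index`
#'   (1 = first exon in transcription order), `start`, `end`.
#' @param validate check invariants (sorted, non-overlapping exons contained
#'   in the span).
#' @return An object of class `gene_models`: a list with elements `genes`
#'   (with derived columns `tss`, `tes`, `n_exons`) and `exons`.
#' @export
gene_models <- function(genes, exons, validate = TRUE) {
  req_g <- c("gene_id", "chrom", "strand", "tx_start", "tx_end")
  req_e <- c("gene_id", "exon_index", "start", "end")
  if (!all(req_g %in% names(genes))) stop("genes must have columns: ", paste(req_g, collapse = ", "))
  if (!all(req_e %in% names(exons))) stop("exons must have columns: ", paste(req_e, collapse = ", "))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
  genes$tes <- ifelse(genes$strand == "+", genes$tx_end, genes$tx_start)
  tab <- table(exons$gene_id)
  genes$n_exons <- as.integer(tab[genes$gene_id])
  obj <- structure(list(genes = genes, exons = exons), class = "gene_models")
  if (validate) validate_gene_models(obj)
  obj
}

validate_gene_models <- function(gm) {
  g <- gm$genes
  if (anyDuplicated(g$gene_id)) stop("duplicated gene ids")
  if (!all(g$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(g$tx_end - g$tx_start < 1)) stop("transcript span must be >= 1 bp")
  if (any(is.na(g$n_exons)) || any(g$n_exons < 1)) stop("every gene needs >= 1 exon")
  ex <- split(gm$exons, gm$exons$gene_id)
  for (gid in g$gene_id) {
    e <- ex[[gid]]
    e <- e[order(e$exon_index), ]
    if (!identical(e$exon_index, seq_len(nrow(e)))) {
      if (!all(e$exon_index == seq_len(nrow(e)))) stop("exon_index must be 1..k for gene ", gid)
    }
    if (any(e$end <= e$start)) stop("zero/negative length exon in gene ", gid)
    rec <- g[g$gene_id == gid, ]
    if (any(e$start < rec$tx_start) || any(e$end > rec$tx_end))
      stop("exon outside transcript span in gene ", gid)
    # genomic order follows transcription order on +, reversed on -
    s <- if (rec$strand == "+") e$start else rev(e$start)
    en <- if (rec$strand == "+") e$end else rev(e$end)
    if (is.unsorted(s, strictly = TRUE) || any(s[-1] < en[-length(en)]))
      stop("exons overlap or are out of transcription order in gene ", gid)
  }
  invisible(gm)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons\n")
  cat("  strands: +", sum(x$genes$strand == "+"), " -", sum(x$genes$strand == "-"), "\n")
  cat("  exons per gene: median", median(x$genes$n_exons),
      "range", paste(range(x$genes$n_exons), collapse = "-"), "\n")
  invisible(x)
}

# exon intervals of one gene in transcription order
gene_exons <- function(gm, gene_id) {
  e <- gm$exons[gm$exons$gene_id == gene_id, , drop = FALSE]
  e[order(e$exon_index), , drop = FALSE]
}

gene_record <- function(gm, gene_id) {
  g <- gm$genes[gm$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) != 1) stop("unknown gene id: ", gene_id)
  g
}

# signed transcription-oriented distance of position from the gene's TSS
# (positive = downstream of the TSS in transcription direction)
signed_tss_distance <- function(pos, gene) {
  if (gene$strand == "+") pos - gene$tss else gene$tss - pos
}
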