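#' Read gene models from BED12 or GFF-like files
#'
#' Coordinates are normalized to the package's internal convention (0-based
#' half-open); strand-aware TSS/TES are derived and exons sorted in
#' transcription order. Records with overlapping exons are rejected with a
#' message.
#'
#' @param path file path.
#' @param format `"bed12"` or `"gff"` (uses `type == "exon"` records
#'   grouped by `Parent`/`gene_id`).
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path, format = c("bed12", "gff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "bed12") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                     !startsWith(lines, "track")]
    for (i in seq_along(lines)) {
      f <- strsplit(lines[i], "\t")[[1]]
      if (length(f) < 12 || anyNA(suppressWarnings(as.numeric(f[c(2, 3, 10)]))))
        stop("malformed BED12 record at line ", i)
    }
    gr <- rtracklayer::import(path, format = "bed")
    genes <- data.frame(gene_id = as.character(gr$name),
                        chrom = as.character(GenomicRanges::seqnames(gr)),
                        strand = as.character(GenomicRanges::strand(gr)),
                        tx_start = GenomicRanges::start(gr) - 1L,
                        tx_end = GenomicRanges::end(gr),
                        stringsAsFactors = FALSE)
    blocks <- gr$blocks
    ex <- lapply(seq_along(gr), function(i) {
      b <- blocks[[i]]
      st <- genes$tx_start[i] + IRanges::start(b) - 1L
      en <- genes$tx_start[i] + IRanges::end(b)
      k <- length(b)
      idx <- if (genes$strand[i] == "+") seq_len(k) else rev(seq_len(k))
      data.frame(gene_id = genes$gene_id[i], exon_index = idx,
                 start = st, end = en, stringsAsFactors = FALSE)
    })
    exons <- do.call(rbind, ex)
  } else {
    gr <- rtracklayer::import(path)
    gr <- gr[tolower(as.character(gr$type)) == "exon"]
    gid <- if (!is.null(gr$Parent) && any(lengths(gr$Parent) > 0))
      vapply(as.list(gr$Parent), function(x) as.character(x)[1], character(1))
    else as.character(gr$gene_id)
    ex0 <- data.frame(gene_id = gid,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      strand = as.character(GenomicRanges::strand(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
    gl <- split(ex0, ex0$gene_id)
    genes <- do.call(rbind, lapply(gl, function(e)
      data.frame(gene_id = e$gene_id[1], chrom = e$chrom[1],
                 strand = e$strand[1], tx_start = min(e$start),
                 tx_end = max(e$end), stringsAsFactors = FALSE)))
    exons <- do.call(rbind, lapply(gl, function(e) {
      e <- e[order(e$start), ]
      k <- nrow(e)
      idx <- if (e$strand[1] == "+") seq_len(k) else rev(seq_len(k))
      data.frame(gene_id = e$gene_id, exon_index = idx, start = e$start,
                 end = e$end, stringsAsFactors = FALSE)
    }))
    rownames(genes) <- rownames(exons) <- NULL
  }
  tryCatch(gene_models(genes, exons),
           error = function(e) stop("invalid gene model record: ",
                                    conditionMessage(e)))
}

#' Write gene models as BED12
#'
#' @param gm a [gene_models()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(gm, path) {
  g <- gm$genes
  lines <- vapply(seq_len(nrow(g)), function(i) {
    e <- gene_exons(gm, g$gene_id[i])
    e <- e[order(e$start), ]  # genomic order for BED blocks
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            g$chrom[i], as.integer(g$tx_start[i]), as.integer(g$tx_end[i]),
            g$gene_id[i], g$strand[i],
            as.integer(g$tx_start[i]), as.integer(g$tx_end[i]), nrow(e),
            paste0(as.integer(e$end - e$start), collapse = ","),
            paste0(as.integer(e$start - g$tx_start[i]), collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF: biallelic records with GT fields become dosages in \{0,1,2\};
#' multi-allelic records are skipped (with a count); missing genotypes are
#' mean-imputed per SNP with a missingness report; all-missing SNPs are
#' dropped with a warning. The MAF floor (> `maf_floor`) is applied on
#' read. Dosage TSV: columns `snp_id`, `chrom`, `pos` then one column per
#' sample.
#'
#' @param path file path.
#' @param format `"vcf"` or `"dosage"`.
#' @param maf_floor exclude SNPs with MAF at or below this (default 0.01).
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage"),
                           maf_floor = 0.01) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT)
    if (any(multi)) message(sum(multi), " multi-allelic record(s) skipped")
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[!multi, , drop = FALSE]
    fix <- fix[!multi, , drop = FALSE]
    dos <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    dos[clean == "0/0"] <- 0
    dos[clean %in% c("0/1", "1/0")] <- 1
    dos[clean == "1/1"] <- 2
    n_miss <- rowSums(is.na(dos))
    all_miss <- n_miss == ncol(dos)
    if (any(all_miss)) warning(sum(all_miss), " all-missing SNP(s) dropped")
    dos <- dos[!all_miss, , drop = FALSE]
    fix <- fix[!all_miss, , drop = FALSE]
    n_miss <- n_miss[!all_miss]
    if (any(n_miss > 0)) {
      message(sum(n_miss > 0), " SNP(s) had missing genotypes (mean-imputed)")
      for (i in which(n_miss > 0)) {
        mi <- is.na(dos[i, ])
        dos[i, mi] <- mean(dos[i, !mi])
      }
    }
    ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                  paste0(fix$CHROM, "_", fix$POS), fix$ID)
    rownames(dos) <- ids
    snps <- data.frame(snp_id = ids, chrom = fix$CHROM,
                       pos = as.integer(fix$POS), stringsAsFactors = FALSE)
  } else {
    tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    snps <- data.frame(snp_id = as.character(tab$snp_id), chrom = tab$chrom,
                       pos = as.integer(tab$pos), stringsAsFactors = FALSE)
    dos <- as.matrix(tab[, setdiff(names(tab), c("snp_id", "chrom", "pos",
                                                 "maf")), drop = FALSE])
    rownames(dos) <- snps$snp_id
  }
  g <- geno_matrix(snps, dos)
  keep <- g$snps$maf > maf_floor
  if (any(!keep)) message(sum(!keep), " SNP(s) at or below the MAF floor dropped")
  subset_snps(g, keep)
}

#' Write genotypes as minimal VCF or dosage TSV
#'
#' @param geno a [geno_matrix()].
#' @param path output path.
#' @param format `"vcf"` (GT-only, integer dosages required) or `"dosage"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path, format = c("vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "vcf") {
    if (any(geno$dosage != round(geno$dosage)))
      stop("VCF output requires integer dosages")
    gt_codes <- c("0/0", "0/1", "1/1")
    header <- c("##fileformat=VCFv4.2",
                paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                       paste(colnames(geno$dosage), collapse = "\t")))
    body <- vapply(seq_len(nrow(geno$snps)), function(i) {
      paste(c(geno$snps$chrom[i], geno$snps$pos[i], geno$snps$snp_id[i],
              "A", "G", ".", "PASS", ".", "GT",
              gt_codes[geno$dosage[i, ] + 1]), collapse = "\t")
    }, character(1))
    writeLines(c(header, body), path)
  } else {
    tab <- cbind(geno$snps[, c("snp_id", "chrom", "pos", "maf")],
                 as.data.frame(geno$dosage, check.names = FALSE))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write / read an expression matrix as TSV triplet
#'
#' `<prefix>_values.tsv` (feature_id + one column per sample),
#' `<prefix>_features.tsv`, `<prefix>_samples.tsv`.
#'
#' @param expr an [expr_matrix()].
#' @param prefix path prefix.
#' @return `prefix` (write) or an [expr_matrix()] (read).
#' @export
write_expression <- function(expr, prefix) {
  vals <- data.frame(feature_id = expr$features$feature_id,
                     expr$values, check.names = FALSE)
  write.table(vals, paste0(prefix, "_values.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(expr$features, paste0(prefix, "_features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(expr$samples, paste0(prefix, "_samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_expression
#' @export
read_expression <- function(prefix) {
  vals <- read.table(paste0(prefix, "_values.tsv"), header = TRUE, sep = "\t",
                     check.names = FALSE, stringsAsFactors = FALSE)
  features <- read.table(paste0(prefix, "_features.tsv"), header = TRUE,
                         sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE)
  samples <- read.table(paste0(prefix, "_samples.tsv"), header = TRUE,
                        sep = "\t", check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(vals[, -1, drop = FALSE])
  rownames(m) <- vals$feature_id
  expr_matrix(m, features, samples)
}
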