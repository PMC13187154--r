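#' Read a (multi-)FASTA genome into a named character vector
#'
#' @param file FASTA path.
#' @return named character vector of uppercase contig sequences; names are
#'   the first whitespace-delimited token of each header.
#' @export
read_genome <- function(file) {
  ss <- Biostrings::readDNAStringSet(file)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Gene models from a GFF3 annotation
#'
#' Returns one row per gene with the coordinates of the chosen anchor
#' feature.  For `feature = "CDS"` (the default, matching promoters defined
#' upstream of the coding sequence) the per-gene CDS span is the minimum
#' start / maximum end over that gene's CDS segments; `"gene"` and
#' `"mRNA"` use those features' own coordinates.
#'
#' @param gff path to a GFF3 file.
#' @param feature `"CDS"`, `"gene"` or `"mRNA"`.
#' @return data frame with columns `gene`, `contig`, `start`, `end`
#'   (1-based inclusive), `strand`.
#' @export
gene_models_from_gff <- function(gff, feature = c("CDS", "gene", "mRNA")) {
  feature <- match.arg(feature)
  g <- rtracklayer::readGFF(gff)
  if (feature == "CDS") {
    sel <- g$type == "CDS"
    if (!any(sel)) stopf("GFF3 '%s' has no CDS features", gff)
    gid <- .gene_of(g)[sel]
    if (anyNA(gid)) stopf("GFF3 '%s': CDS without a resolvable gene", gff)
    d <- data.frame(gene = gid, contig = as.character(g$seqid)[sel],
                    start = g$start[sel], end = g$end[sel],
                    strand = as.character(g$strand)[sel],
                    stringsAsFactors = FALSE)
    sp <- split(d, d$gene)
    out <- do.call(rbind, lapply(sp, function(x)
      data.frame(gene = x$gene[1L], contig = x$contig[1L],
                 start = min(x$start), end = max(x$end),
                 strand = x$strand[1L], stringsAsFactors = FALSE)))
  } else {
    sel <- g$type == feature
    if (!any(sel)) stopf("GFF3 '%s' has no %s features", gff, feature)
    if (anyNA(g$ID[sel])) stopf("GFF3 '%s': %s feature without ID", gff, feature)
    out <- data.frame(gene = as.character(g$ID)[sel],
                      contig = as.character(g$seqid)[sel],
                      start = g$start[sel], end = g$end[sel],
                      strand = as.character(g$strand)[sel],
                      stringsAsFactors = FALSE)
  }
  if (any(!out$strand %in% c("+", "-")))
    stopf("GFF3 '%s': features with missing strand", gff)
  rownames(out) <- NULL
  out
}

#' Extract putative promoter sequences upstream of genes
#'
#' For a `+` strand gene the promoter is the `length` bases immediately
#' 5' of its start (`[start - length, start - 1]`, 1-based inclusive,
#' clipped at the contig edge); for a `-` strand gene it is the reverse
#' complement of `[end + 1, end + length]`.  A flat window is taken
#' regardless of neighbouring features.  Promoters shortened by a contig
#' edge carry `truncated = TRUE`.
#'
#' @param genome named character vector of contig sequences
#'   ([read_genome()]) or a `Biostrings::DNAStringSet`.
#' @param genes gene-model data frame ([gene_models_from_gff()]): columns
#'   `gene`, `contig`, `start`, `end`, `strand`.
#' @param length promoter window size in bp (default 1000).
#' @return data frame with columns `gene`, `contig`, `start`, `end`,
#'   `strand`, `sequence` (uppercase, promoter orientation),
#'   `actual_length`, `truncated`.
#' @export
extract_promoters <- function(genome, genes, length = 1000L) {
  if (inherits(genome, "DNAStringSet"))
    genome <- stats::setNames(toupper(as.character(genome)),
                              sub("\\s.*$", "", names(genome)))
  stopifnot(is.character(genome), !is.null(names(genome)))
  need <- c("gene", "contig", "start", "end", "strand")
  if (!all(need %in% names(genes)))
    stopf("gene table must have columns %s", paste(need, collapse = ", "))
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    gn <- genes$gene[i]; ctg <- genes$contig[i]
    if (!ctg %in% names(genome))
      stopf("gene '%s': contig '%s' absent from the genome", gn, ctg)
    clen <- nchar(genome[[ctg]])
    s <- genes$start[i]; e <- genes$end[i]; strand <- genes$strand[i]
    if (s < 1L || e > clen || s > e)
      stopf("gene '%s': coordinates %d..%d outside contig '%s' (1..%d)",
            gn, s, e, ctg, clen)
    if (strand == "+") {
      from <- max(1L, s - length); to <- s - 1L
      seq <- if (to >= from) substr(genome[[ctg]], from, to) else ""
    } else if (strand == "-") {
      from <- e + 1L; to <- min(clen, e + length)
      seq <- if (to >= from) revcomp(substr(genome[[ctg]], from, to)) else ""
    } else stopf("gene '%s': invalid strand '%s'", gn, strand)
    data.frame(gene = gn, contig = ctg, start = s, end = e, strand = strand,
               sequence = toupper(seq), actual_length = nchar(seq),
               truncated = nchar(seq) < length, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write promoters as FASTA
#'
#' Headers carry the gene id, gene coordinates, strand and truncation flag.
#'
#' @param promoters data frame from [extract_promoters()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_promoter_fasta <- function(promoters, file) {
  hdr <- sprintf(">%s %s:%d-%d(%s)%s", promoters$gene, promoters$contig,
                 promoters$start, promoters$end, promoters$strand,
                 ifelse(promoters$truncated, " truncated", ""))
  keep <- promoters$actual_length > 0L
  writeLines(as.vector(rbind(hdr[keep], promoters$sequence[keep])), file)
  invisible(file)
}
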