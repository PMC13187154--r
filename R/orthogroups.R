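#' Read an HTSeq-style two-column count file
#'
#' Parses the classic headerless `gene<TAB>count` dialect.  Summary rows
#' whose ids begin with `"__"` (`__no_feature`, `__ambiguous`, ...) are
#' removed from the gene mapping and kept in the `summary` element.
#' Fractional counts (as produced by fractional multi-mapper assignment)
#' are accepted with a warning; negative or non-numeric counts and
#' duplicated gene ids are errors reported with their line number.
#'
#' @param file path to the count file.
#' @param sample_id sample label (default: file base name).
#' @param species species tag of the sample.
#' @return object of class `gene_counts`: list with `sample_id`, `species`,
#'   `counts` (named numeric vector) and `summary` (the `__` rows).
#' @export
read_counts <- function(file, sample_id = NULL, species = NA_character_) {
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(file))
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warnf("count file '%s' is empty", file)
    return(structure(list(sample_id = sample_id, species = species,
                          counts = stats::setNames(numeric(0), character(0)),
                          summary = numeric(0)),
                     class = "gene_counts"))
  }
  parts <- strsplit(lines, "[\t,]")
  bad_shape <- which(lengths(parts) != 2L)
  if (length(bad_shape))
    stopf("count file '%s': line %d does not have two fields",
          file, bad_shape[1L])
  gene <- vapply(parts, `[[`, "", 1L)
  val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(val))
    stopf("count file '%s': non-numeric count on line %d",
          file, which(is.na(val))[1L])
  if (any(val < 0))
    stopf("count file '%s': negative count on line %d",
          file, which(val < 0)[1L])
  is_summary <- startsWith(gene, "__")
  summary <- stats::setNames(val[is_summary], gene[is_summary])
  gene <- gene[!is_summary]; val <- val[!is_summary]
  if (anyDuplicated(gene)) {
    ln <- which(!is_summary)[which(duplicated(gene))[1L]]
    stopf("count file '%s': duplicated gene id '%s' (line %d)",
          file, gene[duplicated(gene)][1L], ln)
  }
  if (any(val != floor(val)))
    warnf("count file '%s': fractional counts accepted as nonnegative reals",
          file)
  structure(list(sample_id = sample_id, species = species,
                 counts = stats::setNames(val, gene), summary = summary),
            class = "gene_counts")
}

#' @export
print.gene_counts <- function(x, ...) {
  cat(sprintf("gene_counts: sample '%s' (%s), %d genes, total %.0f\n",
              x$sample_id, x$species, length(x$counts), sum(x$counts)))
  invisible(x)
}

#' Read a sample sheet
#'
#' @param file delimited file with columns `sample`, `species`, `file` and
#'   optionally `group`.
#' @return data frame of those columns.
#' @export
read_sample_sheet <- function(file) {
  d <- read_delim_auto(file)
  need <- c("sample", "species", "file")
  if (!all(need %in% names(d)))
    stopf("sample sheet '%s' must have columns %s", file,
          paste(need, collapse = ", "))
  d
}

#' Read an OrthoFinder Orthogroups.tsv mapping
#'
#' First column is the orthogroup id; every further column is one species,
#' each cell holding a comma(+space)-separated gene list (possibly empty).
#'
#' @param file path to the tab-separated table.
#' @return long data frame with columns `orthogroup`, `species`, `gene`.
#' @export
read_orthogroups <- function(file) {
  d <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE,
                         quote = "", comment.char = "")
  if (ncol(d) < 2L) stopf("orthogroup table '%s' has no species columns", file)
  og <- d[[1L]]
  species <- names(d)[-1L]
  rows <- list()
  for (sp in species) {
    genes <- strsplit(d[[sp]], ",[ ]*")
    nn <- lengths(genes)
    g <- unlist(genes, use.names = FALSE)
    keep <- nzchar(g) & !is.na(g)
    rows[[sp]] <- data.frame(orthogroup = rep(og, nn)[keep], species = sp,
                             gene = g[keep], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  dup <- out[duplicated(out[, c("species", "gene")]), ]
  if (nrow(dup))
    stopf("orthogroup table '%s': gene '%s' (%s) appears in more than one orthogroup",
          file, dup$gene[1L], dup$species[1L])
  rownames(out) <- NULL
  out
}

#' Read a two-column gene-length table
#'
#' @param file delimited file with columns `gene` and `length` (bp).
#' @return named numeric vector of lengths.
#' @export
read_lengths <- function(file) {
  d <- read_delim_auto(file)
  if (!all(c("gene", "length") %in% names(d)))
    stopf("length table '%s' must have columns 'gene' and 'length'", file)
  len <- as.numeric(d$length)
  if (any(!is.finite(len) | len <= 0))
    stopf("length table '%s' has non-positive lengths", file)
  stats::setNames(len, d$gene)
}

# Resolve each feature to its top-level 'gene' ancestor through ID/Parent
# links; features without a gene ancestor resolve to their own ID.
.gene_of <- function(g) {
  id <- as.character(g$ID)
  parent <- vapply(seq_len(nrow(g)), function(i) {
    p <- g$Parent[[i]]
    if (length(p)) as.character(p[1L]) else NA_character_
  }, "")
  known <- !is.na(id)
  parent_of <- stats::setNames(parent[known], id[known])
  type_of <- stats::setNames(as.character(g$type)[known], id[known])
  look <- function(map, k) if (k %in% names(map)) unname(map[[k]]) else NA_character_
  vapply(seq_len(nrow(g)), function(i) {
    cur <- if (!is.na(parent[i])) parent[i] else id[i]
    for (step in 1:10) {
      if (is.na(cur)) return(NA_character_)
      if (identical(look(type_of, cur), "gene")) return(cur)
      nxt <- look(parent_of, cur)
      if (is.na(nxt)) return(cur)
      cur <- nxt
    }
    cur
  }, "")
}

#' Gene lengths from a GFF3 annotation
#'
#' Two length definitions are supported: `gene_span`, the annotated gene
#' footprint `end - start + 1` (GFF3 coordinates are 1-based inclusive),
#' and `exon_union`, the number of bases covered by the union of a gene's
#' exon intervals (overlaps counted once, via interval reduction).
#'
#' @param gff path to a GFF3 file.
#' @param feature `"gene_span"` (default) or `"exon_union"`.
#' @return named numeric vector of lengths in bp.
#' @export
lengths_from_gff <- function(gff, feature = c("gene_span", "exon_union")) {
  feature <- match.arg(feature)
  g <- rtracklayer::readGFF(gff)
  if (any(g$end < g$start))
    stopf("GFF3 '%s' has a feature with end < start", gff)
  if (feature == "gene_span") {
    genes <- g[g$type == "gene", ]
    if (!nrow(genes)) stopf("GFF3 '%s' has no 'gene' features", gff)
    if (anyNA(genes$ID)) stopf("GFF3 '%s': gene feature without an ID", gff)
    return(stats::setNames(genes$end - genes$start + 1, as.character(genes$ID)))
  }
  ex <- g[g$type == "exon", ]
  if (!nrow(ex)) stopf("GFF3 '%s' has no 'exon' features", gff)
  gene_id <- .gene_of(g)[g$type == "exon"]
  if (anyNA(gene_id)) stopf("GFF3 '%s': exon without a resolvable gene", gff)
  by_gene <- split(seq_len(nrow(ex)), gene_id)
  vapply(by_gene, function(i) {
    sum(IRanges::width(IRanges::reduce(IRanges::IRanges(ex$start[i], ex$end[i]))))
  }, 0)
}

#' Sum counts and gene lengths per orthogroup
#'
#' For every sample, member gene counts are summed into their orthogroup;
#' for every species, member gene lengths are summed into a per-species
#' orthogroup length.  Genes counted in a sample but absent from the length
#' table are an error; counted genes absent from the orthogroup map are
#' tallied as unassigned and their count fraction reported per sample.
#' Orthogroups with no members in a species get count 0 and an undefined
#' (`NA`) length there.
#'
#' @param counts a `gene_counts` object or list of them (one per sample).
#' @param lengths named numeric vector of gene lengths
#'   ([read_lengths()] / [lengths_from_gff()]).
#' @param og_map long orthogroup map from [read_orthogroups()].
#' @return data frame of class `og_expression` with one row per
#'   (orthogroup, sample): columns `orthogroup`, `sample`, `species`,
#'   `count`, `length`; attribute `unassigned_fraction` (named per sample).
#' @export
aggregate_orthogroups <- function(counts, lengths, og_map) {
  if (inherits(counts, "gene_counts")) counts <- list(counts)
  stopifnot(all(vapply(counts, inherits, TRUE, "gene_counts")))
  stopifnot(all(c("orthogroup", "species", "gene") %in% names(og_map)))

  ogs <- sort(unique(og_map$orthogroup))
  og_map$skey <- normalize_species(og_map$species)
  # per-species orthogroup length: sum of member lengths known to us
  og_len <- new.env(parent = emptyenv())
  for (sk in unique(og_map$skey)) {
    sub <- og_map[og_map$skey == sk, ]
    have <- sub$gene %in% names(lengths)
    l <- tapply(lengths[sub$gene[have]], sub$orthogroup[have], sum)
    assign(sk, l, envir = og_len)
  }

  rows <- list(); unassigned <- numeric(0)
  for (ct in counts) {
    sk <- normalize_species(ct$species)
    sel <- og_map$skey == sk
    gene2og <- stats::setNames(og_map$orthogroup[sel], og_map$gene[sel])
    g <- names(ct$counts)
    missing_len <- setdiff(g, names(lengths))
    if (length(missing_len))
      stopf("sample '%s': %d counted gene(s) missing from the length table: %s%s",
            ct$sample_id, length(missing_len),
            paste(utils::head(missing_len, 5), collapse = ", "),
            if (length(missing_len) > 5) ", ..." else "")
    og_of <- gene2og[g]
    assigned <- !is.na(og_of)
    tot <- sum(ct$counts)
    unassigned[ct$sample_id] <-
      if (tot > 0) sum(ct$counts[!assigned]) / tot else 0
    cnt <- tapply(ct$counts[assigned], og_of[assigned], sum)
    lens <- get0(sk, envir = og_len, ifnotfound = stats::setNames(numeric(0), character(0)))
    rows[[ct$sample_id]] <- data.frame(
      orthogroup = ogs,
      sample = ct$sample_id,
      species = ct$species,
      count = as.numeric(ifelse(is.na(cnt[ogs]), 0, cnt[ogs])),
      length = as.numeric(lens[ogs]),
      stringsAsFactors = FALSE)
  }
  if (any(unassigned > 0))
    message(sprintf("unassigned count fraction: %s",
                    paste(sprintf("%s %.3f", names(unassigned), unassigned),
                          collapse = ", ")))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "unassigned_fraction") <- unassigned
  class(out) <- c("og_expression", class(out))
  out
}

#' Orthogroup TPM per sample
#'
#' Converts aggregated orthogroup counts and lengths into transcripts per
#' million: per sample, each orthogroup's count/length rate is divided by
#' the sum of rates and scaled by 1e6, so every sample's TPM column sums to
#' one million over the orthogroups included in its normalisation.
#' Orthogroups without a defined length in a sample's species (no members
#' there) are excluded from that sample's normalisation and get `NA` TPM.
#'
#' @param agg output of [aggregate_orthogroups()].
#' @return the input data frame with a `tpm` column added; attribute
#'   `excluded` names, per sample, the orthogroups left out of the
#'   normalisation.
#' @export
compute_tpm <- function(agg) {
  stopifnot(all(c("orthogroup", "sample", "count", "length") %in% names(agg)))
  agg$tpm <- NA_real_
  excluded <- list()
  for (s in unique(agg$sample)) {
    i <- which(agg$sample == s)
    usable <- i[!is.na(agg$length[i]) & agg$length[i] > 0]
    bad <- i[(is.na(agg$length[i]) | agg$length[i] <= 0) & agg$count[i] > 0]
    if (length(bad))
      stopf("sample '%s': orthogroup(s) with counts but no defined length: %s",
            s, paste(agg$orthogroup[bad], collapse = ", "))
    if (!length(usable) || sum(agg$count[usable]) == 0)
      stopf("sample '%s': all counts are zero, TPM undefined", s)
    rate <- agg$count[usable] / agg$length[usable]
    agg$tpm[usable] <- rate / sum(rate) * 1e6
    excluded[[s]] <- agg$orthogroup[setdiff(i, usable)]
  }
  if (any(lengths(excluded) > 0))
    message("orthogroups excluded from normalisation in some samples (no members in that species)")
  attr(agg, "excluded") <- excluded
  agg
}

#' Compare orthogroup expression of each species to a reference species
#'
#' For every orthogroup and every non-reference species, performs a Welch
#' two-sided t test on `log2(TPM + 1)` of that species' replicate samples
#' against the reference species' replicates, and reports the log2 fold
#' change of (pseudocounted) mean TPM.  Comparisons with fewer than two
#' replicates on either side are skipped with a logged reason.  Replicate
#' vectors that are identical constants on both sides give `log2fc` 0 and
#' p = 1.
#'
#' @param expr TPM table from [compute_tpm()] (columns `orthogroup`,
#'   `sample`, `species`, `tpm`).
#' @param reference name of the reference species.
#' @return data frame with columns `orthogroup`, `species`, `n_ref`,
#'   `n_other`, `mean_ref`, `mean_other`, `log2fc`, `t`, `p_value`,
#'   `p_adj` (Benjamini-Hochberg within species).
#' @export
compare_to_reference <- function(expr, reference) {
  stopifnot(all(c("orthogroup", "sample", "species", "tpm") %in% names(expr)))
  key <- normalize_species(expr$species)
  rkey <- normalize_species(reference)
  if (!any(key == rkey))
    stopf("reference species '%s' not present in the expression table",
          reference)
  ref <- expr[key == rkey, ]
  others <- unique(expr$species[key != rkey])
  skipped <- character(0)
  rows <- list()
  for (sp in others) {
    oth <- expr[expr$species == sp, ]
    for (og in unique(expr$orthogroup)) {
      a <- oth$tpm[oth$orthogroup == og]
      b <- ref$tpm[ref$orthogroup == og]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2L || length(b) < 2L) {
        skipped <- c(skipped, sprintf("%s/%s", sp, og))
        next
      }
      la <- log2(a + 1); lb <- log2(b + 1)
      if (stats::sd(la) == 0 && stats::sd(lb) == 0) {
        tt <- list(statistic = 0,
                   p.value = if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0)
      } else {
        w <- stats::t.test(la, lb, var.equal = FALSE)
        tt <- list(statistic = unname(w$statistic), p.value = w$p.value)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        orthogroup = og, species = sp,
        n_ref = length(b), n_other = length(a),
        mean_ref = mean(b), mean_other = mean(a),
        log2fc = log2((mean(a) + 1) / (mean(b) + 1)),
        t = tt$statistic, p_value = tt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  if (length(skipped))
    message("comparisons skipped (fewer than 2 replicates): ",
            paste(utils::head(skipped, 10), collapse = ", "),
            if (length(skipped) > 10) ", ..." else "")
  if (!length(rows)) stopf("no comparisons could be made")
  out <- do.call(rbind, rows)
  out$p_adj <- stats::ave(out$p_value, out$species,
                          FUN = function(p) stats::p.adjust(p, "BH"))
  rownames(out) <- NULL
  out
}
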