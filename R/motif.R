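# IUPAC nucleotide codes as base sets over A/C/G/T.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T"))

BASE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse-complement a DNA string
#'
#' Handles the full IUPAC alphabet (`N` stays `N`, `R` becomes `Y`, ...).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("CGGAAACCG")
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(comp, function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""), "",
    USE.NAMES = FALSE)
}

#' Parse an IUPAC degenerate motif
#'
#' Accepts a motif written in IUPAC nucleotide codes with optional
#' run-length shorthand `X{k}`, e.g. the Gal4p-binding consensus
#' `"CGGN{11}CCG"` (17 bp after expansion).
#'
#' @param pattern_text the motif string.
#' @return object of class `iupac_motif`: list with `pattern` (expanded
#'   string), `length`, and `base_sets` (list of allowed-base character
#'   vectors per position).
#' @export
#' @examples
#' parse_motif("CGGN{11}CCG")$length   # 17
parse_motif <- function(pattern_text) {
  stopifnot(is.character(pattern_text), length(pattern_text) == 1L)
  txt <- toupper(gsub("\\s", "", pattern_text))
  if (grepl("\\{", txt)) {
    if (!grepl("^([A-Z](\\{[0-9]+\\})?)+$", txt))
      stopf("malformed run-length shorthand in motif '%s'", pattern_text)
    m <- gregexpr("[A-Z](\\{[0-9]+\\})?", txt)[[1L]]
    toks <- regmatches(txt, list(m))[[1L]]
    txt <- paste(vapply(toks, function(tk) {
      base <- substr(tk, 1L, 1L)
      k <- if (nchar(tk) > 1L)
        as.integer(sub("^[A-Z]\\{([0-9]+)\\}$", "\\1", tk)) else 1L
      strrep(base, k)
    }, ""), collapse = "")
  }
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad))
    stopf("invalid IUPAC code '%s' at motif position %d", chars[bad[1L]],
          bad[1L])
  if (!length(chars)) stopf("empty motif")
  structure(list(pattern = txt,
                 length = length(chars),
                 base_sets = IUPAC_SETS[chars]),
            class = "iupac_motif")
}

#' @export
print.iupac_motif <- function(x, ...) {
  ndeg <- sum(lengths(x$base_sets) > 1L)
  cat(sprintf("IUPAC motif %s (%d bp, %d degenerate position%s)\n",
              x$pattern, x$length, ndeg, if (ndeg == 1L) "" else "s"))
  invisible(x)
}

# complement of a base set
.comp_set <- function(s) sort(unname(BASE_COMPLEMENT[s]))

#' Is a degenerate motif its own reverse complement?
#'
#' True when reversing the motif and complementing each position's base set
#' reproduces the original sequence of base sets.  A self-reverse-
#' complementary (palindromic) consensus, like CGG-N11-CCG, matches a
#' genomic window on the forward strand exactly when it matches it on the
#' reverse strand, so forward-only scanning already finds every site.
#'
#' @param motif an [parse_motif()] object.
#' @return logical scalar.
#' @export
#' @examples
#' is_self_reverse_complement(parse_motif("CGGN{11}CCG"))  # TRUE
is_self_reverse_complement <- function(motif) {
  stopifnot(inherits(motif, "iupac_motif"))
  sets <- lapply(motif$base_sets, function(s) sort(unname(s)))
  rc <- rev(lapply(sets, .comp_set))
  identical(unname(sets), unname(rc))
}

# integer-encode a sequence: A=1 C=2 G=3 T=4, anything else (incl. N) 0 —
# ambiguity bases in the subject never match (conservative).
.encode_dna <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  code <- match(chars, c("A", "C", "G", "T"))
  code[is.na(code)] <- 0L
  code
}

# allowed[j, b]: does base b satisfy motif position j?
.allowed_matrix <- function(motif) {
  m <- matrix(FALSE, motif$length, 4L,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  for (j in seq_len(motif$length)) m[j, motif$base_sets[[j]]] <- TRUE
  m
}

# 0-based offsets of all (possibly overlapping) forward-strand matches
.scan_forward <- function(code, allowed) {
  n <- length(code); m <- nrow(allowed)
  if (n < m) return(integer(0))
  nw <- n - m + 1L
  valid <- rep(TRUE, nw)
  for (j in seq_len(m)) {
    cj <- code[j:(j + nw - 1L)]
    vj <- cj > 0L
    vj[vj] <- allowed[j, cj[vj]]
    valid <- valid & vj
    if (!any(valid)) return(integer(0))
  }
  which(valid) - 1L
}

#' Count degenerate motif matches in a promoter sequence
#'
#' Finds all (possibly overlapping) offsets at which every position of the
#' sequence lies in the motif's allowed base set.  Ambiguity bases (`N`) in
#' the sequence never match.  With `strands = "both"` the reverse
#' complement is also scanned and reverse hits are reported by the forward
#' coordinate of the same genomic window, de-duplicating windows matched on
#' both strands (for a self-reverse-complementary motif, both modes give
#' identical results).
#'
#' @param sequence a single DNA string over `A`, `C`, `G`, `T`, `N`.
#' @param motif an [parse_motif()] object (a string is parsed for
#'   convenience).
#' @param strands `"forward"` (default) or `"both"`.
#' @return object of class `motif_hits`: list with `offsets` (0-based,
#'   strictly increasing window starts), `count`, `strands` and the motif
#'   `pattern`.  Sequences shorter than the motif yield zero hits.
#' @export
#' @examples
#' count_sites(paste0("CGG", strrep("A", 11), "CCG"), "CGGN{11}CCG")$count
count_sites <- function(sequence, motif, strands = c("forward", "both")) {
  strands <- match.arg(strands)
  if (is.character(motif)) motif <- parse_motif(motif)
  stopifnot(inherits(motif, "iupac_motif"),
            is.character(sequence), length(sequence) == 1L)
  code <- .encode_dna(sequence)
  allowed <- .allowed_matrix(motif)
  off <- .scan_forward(code, allowed)
  if (strands == "both") {
    n <- length(code)
    rc_off <- .scan_forward(.encode_dna(revcomp(sequence)), allowed)
    # reverse-strand match at rc offset o covers forward window n - o - m
    off <- sort(unique(c(off, n - rc_off - motif$length)))
  }
  structure(list(offsets = as.integer(off), count = length(off),
                 strands = strands, pattern = motif$pattern),
            class = "motif_hits")
}

#' @export
print.motif_hits <- function(x, ...) {
  cat(sprintf("%d match(es) of %s (%s strand%s)", x$count, x$pattern,
              x$strands, if (x$strands == "both") "s" else ""))
  if (x$count) cat(" at 0-based offsets:", paste(x$offsets, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' Scan a set of promoters for a motif
#'
#' Vectorised convenience wrapper around [count_sites()].
#'
#' @param promoters data frame from [extract_promoters()] (columns `gene`,
#'   `sequence`) or a named character vector of sequences.
#' @param motif motif string or [parse_motif()] object.
#' @param strands `"forward"` or `"both"`.
#' @return data frame with columns `gene`, `count`, `offsets`
#'   (comma-separated 0-based positions).
#' @export
scan_promoters <- function(promoters, motif, strands = c("forward", "both")) {
  strands <- match.arg(strands)
  if (is.character(motif)) motif <- parse_motif(motif)
  if (is.character(promoters))
    promoters <- data.frame(gene = names(promoters) %||%
                              paste0("seq", seq_along(promoters)),
                            sequence = unname(promoters),
                            stringsAsFactors = FALSE)
  hits <- lapply(promoters$sequence, count_sites, motif = motif,
                 strands = strands)
  data.frame(gene = promoters$gene,
             count = vapply(hits, `[[`, 0L, "count"),
             offsets = vapply(hits, function(h)
               paste(h$offsets, collapse = ","), ""),
             stringsAsFactors = FALSE)
}

#' Maximum per-family motif-site count per species
#'
#' When a species carries several members (in-paralogs) of a gene family,
#' the member whose promoter has the most predicted binding sites is the
#' one summarised, mirroring the "ortholog with the highest number of
#' binding sites" convention for visualisation.
#'
#' @param hits data frame with columns `gene` and `count`
#'   (see [scan_promoters()]); genes with `NA` counts (missing promoters)
#'   contribute nothing and are logged.
#' @param family_map named character vector or data frame (`gene`,
#'   `family`) assigning genes to families.
#' @param species_map named character vector or data frame (`gene`,
#'   `species`) assigning genes to species.
#' @return integer matrix species x family of maximal site counts; families
#'   with no member in a species are `NA`.
#' @export
summarize_by_family <- function(hits, family_map, species_map) {
  as_named <- function(m, val) {
    if (is.data.frame(m)) stats::setNames(as.character(m[[val]]), m$gene)
    else m
  }
  family_map <- as_named(family_map, "family")
  species_map <- as_named(species_map, "species")
  fam <- family_map[hits$gene]
  sp <- species_map[hits$gene]
  if (anyNA(fam) || anyNA(sp))
    stopf("genes without family/species assignment: %s",
          paste(utils::head(hits$gene[is.na(fam) | is.na(sp)], 5),
                collapse = ", "))
  drop <- is.na(hits$count)
  if (any(drop))
    message("genes without a promoter dropped from the summary: ",
            paste(hits$gene[drop], collapse = ", "))
  h <- hits[!drop, ]; fam <- fam[!drop]; sp <- sp[!drop]
  species <- sort(unique(sp)); families <- sort(unique(fam))
  out <- matrix(NA_integer_, length(species), length(families),
                dimnames = list(species, families))
  agg <- tapply(h$count, list(sp, fam), max)
  out[rownames(agg), colnames(agg)] <- as.integer(agg)
  out
}

#' Mutate a sequence until a motif no longer matches anywhere
#'
#' Emulates the site-directed mutagenesis used to ablate predicted binding
#' sites in a reporter-construct promoter: within each matched window,
#' bases are substituted only at the motif's non-degenerate positions (the
#' CGG/CCG triplets for the default Gal4p consensus), replacements being
#' drawn deterministically from the seed among bases that break the match
#' on both strands.  The procedure is greedy: one edit per remaining hit
#' per round (escalating across that hit's fixed runs if rescanning reveals
#' persisting or newly created matches), and the sequence is rescanned on
#' both strands between rounds until no match remains anywhere.
#'
#' @param sequence DNA string previously scanned with `motif`.
#' @param motif motif string or [parse_motif()] object.
#' @param seed integer seed making the substitutions reproducible.
#' @param max_rounds escalation cap; exceeding it is an error
#'   (pathological input).
#' @return the mutated sequence, with attribute `edits` (data frame `pos`,
#'   `from`, `to`, 1-based positions).  A sequence without hits is
#'   returned unchanged.
#' @export
ablate_sites <- function(sequence, motif, seed = 1L, max_rounds = 10L) {
  if (is.character(motif)) motif <- parse_motif(motif)
  fixed_pos <- which(lengths(motif$base_sets) < 4L)
  if (!length(fixed_pos))
    stopf("motif '%s' has no non-degenerate positions to mutate",
          motif$pattern)
  # contiguous runs of fixed positions ("triplets" for the Gal4p consensus)
  runs <- split(fixed_pos, cumsum(c(1L, diff(fixed_pos) != 1L)))
  set.seed(seed)
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  edits <- list()
  for (round in seq_len(max_rounds)) {
    h <- count_sites(paste(chars, collapse = ""), motif, strands = "both")
    if (h$count == 0L) {
      out <- paste(chars, collapse = "")
      attr(out, "edits") <- if (length(edits))
        do.call(rbind, edits) else
        data.frame(pos = integer(0), from = character(0), to = character(0))
      return(out)
    }
    for (o in h$offsets) {
      # round 1 edits one position (in the first fixed run); later rounds
      # escalate across further runs of the same window
      use_runs <- runs[seq_len(min(round, length(runs)))]
      edited <- FALSE
      for (r in use_runs) {
        for (j in r) {
          pos <- o + j           # 1-based sequence position
          fwd_set <- motif$base_sets[[j]]
          rev_set <- .comp_set(motif$base_sets[[motif$length - j + 1L]])
          ok <- setdiff(c("A", "C", "G", "T"), union(fwd_set, rev_set))
          if (!length(ok)) next
          new <- ok[sample.int(length(ok), 1L)]
          if (chars[pos] != new) {
            edits[[length(edits) + 1L]] <-
              data.frame(pos = pos, from = chars[pos], to = new)
            chars[pos] <- new
            edited <- TRUE
            break
          }
        }
        if (edited && round == 1L) break
      }
    }
  }
  stopf("could not remove all motif matches within %d rounds", max_rounds)
}
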