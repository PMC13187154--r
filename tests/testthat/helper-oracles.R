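# Independent, deliberately naive oracles.  Each recomputes a quantity by a
# different route than the package (explicit normal equations, explicit
# matrix inverses, per-base loops) so agreement is evidence, not tautology.

# closed-form OLS via the normal equations: c(intercept, slope)
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  unname(drop(solve(t(X) %*% X, t(X) %*% y)))
}

# GLS by explicit inversion of the covariance matrix
gls_oracle <- function(y, x, C) {
  X <- cbind(1, x)
  Ci <- solve(C)
  beta <- solve(t(X) %*% Ci %*% X, t(X) %*% Ci %*% y)
  e <- y - X %*% beta
  df <- length(y) - 2L
  s2 <- drop(t(e) %*% Ci %*% e) / df
  V <- s2 * solve(t(X) %*% Ci %*% X)
  list(beta = drop(beta), se = sqrt(diag(V)))
}

# Brownian covariance from scratch: shared branch length of root-to-tip
# edge paths for every tip pair
bm_cov_oracle <- function(tree) {
  n <- ape::Ntip(tree)
  paths <- lapply(seq_len(n), function(tip) {
    e <- integer(0); cur <- tip
    repeat {
      row <- which(tree$edge[, 2] == cur)
      if (!length(row)) break
      e <- c(e, row); cur <- tree$edge[row, 1]
    }
    e
  })
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in i:n) {
    shared <- intersect(paths[[i]], paths[[j]])
    C[i, j] <- C[j, i] <- sum(tree$edge.length[shared])
  }
  C
}

# O(n*m) character-by-character motif scan; returns 0-based offsets
naive_scan <- function(seq, motif, strands = "forward") {
  sets <- motif$base_sets
  m <- length(sets)
  one <- function(s) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
    n <- length(chars)
    offs <- integer(0)
    if (n >= m) for (o in 0:(n - m)) {
      ok <- TRUE
      for (j in 1:m) if (!(chars[o + j] %in% sets[[j]])) { ok <- FALSE; break }
      if (ok) offs <- c(offs, o)
    }
    offs
  }
  offs <- one(seq)
  if (strands == "both") {
    roffs <- one(revcomp(seq))
    offs <- sort(unique(c(offs, nchar(seq) - roffs - m)))
  }
  offs
}

# closed-form Welch t test
welch_oracle <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  tt <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = tt, p = 2 * pt(-abs(tt), df))
}

rand_dna <- function(n, alphabet = c("A", "C", "G", "T"))
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

# extraction oracle: reverse-complement the whole contig and apply the
# plus-strand rule to the mirrored coordinates
mirror_promoter_oracle <- function(contig, start, end, strand, len) {
  if (strand == "+") {
    from <- max(1L, start - len); to <- start - 1L
    if (to >= from) substr(contig, from, to) else ""
  } else {
    rc <- revcomp(contig)
    L <- nchar(contig)
    s2 <- L - end + 1L              # gene start on the mirrored strand
    from <- max(1L, s2 - len); to <- s2 - 1L
    if (to >= from) substr(rc, from, to) else ""
  }
}

# naive per-gene loop for orthogroup aggregation
aggregate_oracle <- function(counts_list, lengths, og_map) {
  out <- list()
  for (ct in counts_list) {
    sk <- normalize_species(ct$species)
    for (og in sort(unique(og_map$orthogroup))) {
      members <- og_map$gene[og_map$orthogroup == og &
                               normalize_species(og_map$species) == sk]
      cnt <- 0
      for (g in names(ct$counts)) if (g %in% members) cnt <- cnt + ct$counts[[g]]
      len <- if (length(members)) as.numeric(sum(lengths[members])) else NA_real_
      out[[paste(og, ct$sample_id)]] <-
        data.frame(orthogroup = og, sample = ct$sample_id,
                   count = cnt, length = len)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# build a random small gene_counts/og_map/lengths instance
random_expression_instance <- function(n_og = 5, n_species = 3, n_samples = 2,
                                       p_absent = 0.2) {
  ogs <- sprintf("OG%03d", seq_len(n_og))
  species <- sprintf("sp%d", seq_len(n_species))
  og_map <- do.call(rbind, lapply(species, function(sp) {
    rows <- lapply(ogs, function(og) {
      if (runif(1) < p_absent) return(NULL)
      ng <- sample(1:3, 1)
      data.frame(orthogroup = og, species = sp,
                 gene = sprintf("%s_%s_g%d", sp, og, seq_len(ng)))
    })
    do.call(rbind, rows)
  }))
  lengths <- setNames(sample(200:2000, nrow(og_map)), og_map$gene)
  counts <- list()
  for (sp in species) for (r in seq_len(n_samples)) {
    genes <- og_map$gene[og_map$species == sp]
    id <- sprintf("%s_r%d", sp, r)
    counts[[id]] <- structure(
      list(sample_id = id, species = sp,
           counts = setNames(as.numeric(rpois(length(genes), 100)), genes),
           summary = numeric(0)),
      class = "gene_counts")
  }
  list(counts = counts, og_map = og_map, lengths = lengths)
}
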