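# Seeded generators with recorded ground truth for every pipeline stage.
# One root seed derives a named substream per generator (substream_seed),
# so adding a generator never perturbs the draws of another.

#' Simulate a phenol-red acidification plate experiment
#'
#' Generates paired carbon (2% dextrose) and water-control wells for each
#' strain and replicate: linear pH trajectories `pH(t) = pH0 + slope * t`
#' sampled every 3 minutes over 90 minutes (31 timepoints by default),
#' converted to absorbance through the inverse of a known standard curve
#' and perturbed with Gaussian absorbance noise.  The default true slopes
#' reproduce the two headline phenotypes of the yeast screen the package
#' supports: a rapid acidifier with dextrose-dependent ECAR -0.032 pH/h
#' and a low-ECAR species at +0.022 pH/h.
#'
#' @param seed root seed; every draw is derived from it.
#' @param strains data frame with columns `strain`, `slope_carbon`,
#'   `slope_control` (pH/h); default the two phenotypes above.
#' @param n_replicates biological replicates per strain (default 3).
#' @param noise_sd Gaussian absorbance noise standard deviation
#'   (default 0.005 absorbance units).
#' @param timepoints number of reads (default 31).
#' @param duration_min assay length in minutes (default 90).
#' @param ph0 starting medium pH (default 6.8, the assay medium).
#' @param curve_slope,curve_intercept the true standard curve
#'   `pH = slope * A560 + intercept` used for the inversion.
#' @param calib_ph pH values of the written calibration table (noiseless).
#' @param dir optional output directory; when given, `plate.csv`,
#'   `layout.csv`, `calibration.csv` and `truth.csv` are written there.
#' @return list with `plate` (long well/time_min/a560), `layout`,
#'   `calibration`, `truth` (list: `strains` incl. true `ecar`,
#'   `wells` per-well true slopes, curve parameters, `noise_sd`) and,
#'   if `dir` was given, `paths`.
#' @export
simulate_plate <- function(seed = 1L,
                           strains = NULL,
                           n_replicates = 3L,
                           noise_sd = 0.005,
                           timepoints = 31L,
                           duration_min = 90,
                           ph0 = 6.8,
                           curve_slope = 1,
                           curve_intercept = 6.4,
                           calib_ph = seq(6.5, 7.5, by = 0.1),
                           dir = NULL) {
  if (curve_slope == 0) stopf("standard-curve slope must be nonzero")
  stopifnot(n_replicates >= 1L, timepoints >= 3L, noise_sd >= 0)
  if (is.null(strains))
    strains <- data.frame(strain = c("rapid_ecar", "low_ecar"),
                          slope_carbon = c(-0.037, 0.017),
                          slope_control = c(-0.005, -0.005),
                          stringsAsFactors = FALSE)
  set.seed(substream_seed(seed, "plate"))
  tm <- seq(0, duration_min, length.out = timepoints)

  layout <- expand.grid(condition = c("carbon", "control"),
                        replicate = seq_len(n_replicates),
                        strain = strains$strain,
                        stringsAsFactors = FALSE)[, c("strain", "condition",
                                                      "replicate")]
  layout$well <- sprintf("%s%02d",
                         LETTERS[(seq_len(nrow(layout)) - 1L) %/% 12L + 1L],
                         (seq_len(nrow(layout)) - 1L) %% 12L + 1L)
  layout <- layout[, c("well", "strain", "condition", "replicate")]
  slope_of <- function(strain, cond) {
    i <- match(strain, strains$strain)
    if (cond == "carbon") strains$slope_carbon[i] else strains$slope_control[i]
  }
  layout$true_slope <- mapply(slope_of, layout$strain, layout$condition)

  plate <- do.call(rbind, lapply(seq_len(nrow(layout)), function(i) {
    ph <- ph0 + layout$true_slope[i] * tm / 60
    a <- (ph - curve_intercept) / curve_slope + rnorm(length(tm), 0, noise_sd)
    data.frame(well = layout$well[i], time_min = tm, a560 = a,
               stringsAsFactors = FALSE)
  }))
  calibration <- data.frame(ph = calib_ph,
                            a560 = (calib_ph - curve_intercept) / curve_slope)
  strains$ecar <- strains$slope_carbon - strains$slope_control
  truth <- list(strains = strains,
                wells = layout,
                curve_slope = curve_slope, curve_intercept = curve_intercept,
                ph0 = ph0, noise_sd = noise_sd)
  out <- list(plate = plate, layout = layout[, 1:4], calibration = calibration,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, c("plate.csv", "layout.csv", "calibration.csv",
                              "truth.csv"))
    utils::write.csv(plate, paths[1L], row.names = FALSE, quote = FALSE)
    utils::write.csv(out$layout, paths[2L], row.names = FALSE, quote = FALSE)
    utils::write.csv(calibration, paths[3L], row.names = FALSE, quote = FALSE)
    utils::write.csv(layout, paths[4L], row.names = FALSE, quote = FALSE)
    out$paths <- stats::setNames(paths, c("plate", "layout", "calibration",
                                          "truth"))
  }
  out
}

#' Simulate a phylogeny with coupled gene-family counts and a trait
#'
#' Grows a pure-birth (Yule) tree, rescales it to depth 1 (so the Brownian
#' rate is the trait variance at the tips), draws per-family copy numbers
#' as Poisson counts whose mean is shifted in one clade (giving the
#' predictor itself phylogenetic signal, which is what makes the
#' PGLS-versus-OLS contrast visible), and generates the trait as
#' `beta * total_copies + e`, `e ~ N(0, sigma2 * C)` accumulated along the
#' branches.
#'
#' @param seed root seed.
#' @param n_taxa number of tips (>= 4).
#' @param n_families number of gene families.
#' @param beta true regression coefficient of the trait on the total copy
#'   number (default -0.005 pH/h per copy: more glycolytic copies, more
#'   negative ECAR).
#' @param sigma2 Brownian rate; trait variance at the tips since the tree
#'   has depth 1 (default 4e-4, i.e. tip SD 0.02 pH/h).
#' @param base_mean,shifted_mean Poisson copy-number means outside/inside
#'   the shifted clade.
#' @param family_names optional family column names.
#' @param dir optional output directory (`tree.nwk`, `counts.tsv`,
#'   `trait.tsv`, `truth.csv`).
#' @return list with `tree` (`phylo`, depth 1), `counts` (species x family
#'   data frame incl. `total`), `trait` (`species`, `mean_ecar`), `truth`
#'   (list: `beta`, `sigma2`, `shifted_species`) and optional `paths`.
#' @export
simulate_tree_trait_counts <- function(seed = 1L, n_taxa = 32L,
                                       n_families = 12L,
                                       beta = -0.005, sigma2 = 4e-4,
                                       base_mean = 2, shifted_mean = 4,
                                       family_names = NULL, dir = NULL) {
  if (n_taxa < 4L) stopf("need at least 4 taxa, got %d", n_taxa)
  stopifnot(sigma2 >= 0, n_families >= 1L)
  if (is.null(family_names))
    family_names <- c("HXK", "PGI", "PFK", "FBA", "TPI", "TDH", "PGK",
                      "GPM", "ENO", "PYK", "PDC", "HXT")[
                        seq_len(min(n_families, 12L))]
  if (length(family_names) < n_families)
    family_names <- c(family_names,
                      sprintf("FAM%02d", seq_len(n_families - length(family_names))))
  set.seed(substream_seed(seed, "tree_trait_counts"))

  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%03d", seq_len(n_taxa))

  # shifted clade: an internal node whose clade covers 20-60% of the tips
  # (descendant tip counts accumulated over a postorder edge traversal)
  cnt <- c(rep(1L, n_taxa), integer(tree$Nnode))
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(eo))) cnt[eo[i, 1L]] <- cnt[eo[i, 1L]] + cnt[eo[i, 2L]]
  sizes <- cnt[(n_taxa + 1L):(n_taxa + tree$Nnode)]
  cand <- which(sizes >= 0.2 * n_taxa & sizes <= 0.6 * n_taxa)
  node <- if (length(cand)) n_taxa + cand[sample.int(length(cand), 1L)]
          else n_taxa + which.min(abs(sizes - 0.4 * n_taxa))
  shifted <- ape::extract.clade(tree, node)$tip.label

  mu <- ifelse(tree$tip.label %in% shifted, shifted_mean, base_mean)
  counts <- sapply(family_names, function(f) rpois(n_taxa, mu))
  rownames(counts) <- tree$tip.label
  total <- rowSums(counts)

  C <- bm_covariance(tree)
  noise <- if (sigma2 > 0)
    sqrt(sigma2) * drop(t(chol(C)) %*% rnorm(n_taxa)) else numeric(n_taxa)
  trait <- beta * total + noise

  counts_df <- data.frame(species = tree$tip.label, counts, total = total,
                          stringsAsFactors = FALSE, row.names = NULL,
                          check.names = FALSE)
  trait_df <- data.frame(species = tree$tip.label, mean_ecar = unname(trait),
                         stringsAsFactors = FALSE)
  out <- list(tree = tree, counts = counts_df, trait = trait_df,
              truth = list(beta = beta, sigma2 = sigma2,
                           shifted_species = shifted))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, c("tree.nwk", "counts.tsv", "trait.tsv",
                              "truth.csv"))
    ape::write.tree(tree, paths[1L])
    utils::write.table(counts_df, paths[2L], sep = "\t", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(trait_df, paths[3L], sep = "\t", row.names = FALSE,
                       quote = FALSE)
    utils::write.csv(data.frame(key = c("beta", "sigma2", "shifted_species"),
                                value = c(beta, sigma2,
                                          paste(shifted, collapse = ";"))),
                     paths[4L], row.names = FALSE, quote = FALSE)
    out$paths <- stats::setNames(paths, c("tree", "counts", "trait", "truth"))
  }
  out
}

#' Simulate a cross-species orthogroup expression experiment
#'
#' Emulates the two-rapid versus two-low species design: every orthogroup
#' has 1-3 member genes per species (lengths uniform on 500-5000 bp), gene
#' counts are negative binomial around an orthogroup-level mean split
#' equally across members, and a designated subset of orthogroups carries
#' a planted fold change between the rapid and low groups (rapid up).
#' Written files use the standard dialects: headerless two-column HTSeq
#' count files with `__` summary rows, an OrthoFinder-style
#' `Orthogroups.tsv`, a gene-length table and a sample sheet.
#'
#' @param seed root seed.
#' @param n_orthogroups number of orthogroups.
#' @param n_de number of orthogroups with the planted fold change.
#' @param fold_change planted fold change (rapid over low; default 4).
#' @param dispersion negative-binomial dispersion (`variance =
#'   mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param n_replicates samples per species (default 4).
#' @param species_groups named character vector mapping species to group
#'   labels, with exactly the groups `"rapid"` and `"low"`.
#' @param mean_log,sd_log log-normal parameters of the orthogroup baseline
#'   expression level (expected reads per kb of orthogroup length).
#' @param dir optional output directory.
#' @return list with `counts` (list of `gene_counts`), `sample_sheet`,
#'   `og_map` (long orthogroup map), `lengths` (named vector), `truth`
#'   (list: `fold_changes` per orthogroup, `de_orthogroups`, `theta`
#'   baseline expression levels, `dispersion`) and optional `paths`.
#' @export
simulate_expression <- function(seed = 1L, n_orthogroups = 60L, n_de = 6L,
                                fold_change = 4, dispersion = 0.1,
                                n_replicates = 4L,
                                species_groups = c(Sat_dispora = "rapid",
                                                   Sat_hagleri = "rapid",
                                                   Sat_mendoncae = "low",
                                                   Sat_silvae = "low"),
                                mean_log = log(200), sd_log = 1,
                                dir = NULL) {
  if (dispersion < 0) stopf("dispersion must be nonnegative")
  stopifnot(n_orthogroups >= 1L, n_de <= n_orthogroups, n_replicates >= 1L,
            all(species_groups %in% c("rapid", "low")))
  set.seed(substream_seed(seed, "expression"))
  species <- names(species_groups)
  ogs <- sprintf("OG%07d", seq_len(n_orthogroups))

  # gene membership: 1-3 genes per orthogroup per species
  og_map <- do.call(rbind, lapply(species, function(sp) {
    ng <- sample(1:3, n_orthogroups, replace = TRUE)
    data.frame(orthogroup = rep(ogs, ng), species = sp,
               gene = sprintf("%s_g%05d", sp, seq_len(sum(ng))),
               stringsAsFactors = FALSE)
  }))
  lengths <- stats::setNames(round(runif(nrow(og_map), 500, 5000)),
                             og_map$gene)

  # theta: orthogroup expression level in expected reads per kb, so that
  # expected gene counts are proportional to gene length (as in RNA-seq)
  # and orthogroup TPM recovers theta irrespective of gene membership
  theta <- stats::setNames(stats::rlnorm(n_orthogroups, mean_log, sd_log),
                           ogs)
  de_ogs <- sort(sample(ogs, n_de))
  fold_changes <- stats::setNames(rep(1, n_orthogroups), ogs)
  fold_changes[de_ogs] <- fold_change

  draw <- function(mu_vec) {
    if (dispersion > 0) rnbinom(length(mu_vec), mu = mu_vec,
                                size = 1 / dispersion)
    else rpois(length(mu_vec), mu_vec)
  }
  counts <- list(); sheet <- list()
  for (sp in species) {
    members <- og_map[og_map$species == sp, ]
    mu_gene <- theta[members$orthogroup] * lengths[members$gene] / 1000
    if (species_groups[[sp]] == "rapid")
      mu_gene <- mu_gene * fold_changes[members$orthogroup]
    for (r in seq_len(n_replicates)) {
      sample_id <- sprintf("%s_r%d", sp, r)
      v <- stats::setNames(as.numeric(draw(mu_gene)), members$gene)
      counts[[sample_id]] <- structure(
        list(sample_id = sample_id, species = sp, counts = v,
             summary = c(`__no_feature` = as.numeric(rpois(1L, 50)),
                         `__ambiguous` = as.numeric(rpois(1L, 10)))),
        class = "gene_counts")
      sheet[[sample_id]] <- data.frame(
        sample = sample_id, species = sp,
        file = paste0(sample_id, ".counts.tsv"),
        group = species_groups[[sp]], stringsAsFactors = FALSE)
    }
  }
  sample_sheet <- do.call(rbind, c(sheet, list(make.row.names = FALSE)))
  out <- list(counts = counts, sample_sheet = sample_sheet, og_map = og_map,
              lengths = lengths,
              truth = list(fold_changes = fold_changes,
                           de_orthogroups = de_ogs,
                           theta = theta,
                           dispersion = dispersion,
                           species_groups = species_groups))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    for (ct in counts) {
      p <- file.path(dir, paste0(ct$sample_id, ".counts.tsv"))
      writeLines(c(paste(names(ct$counts), ct$counts, sep = "\t"),
                   paste(names(ct$summary), ct$summary, sep = "\t")), p)
      paths[ct$sample_id] <- p
    }
    ss <- file.path(dir, "sample_sheet.tsv")
    utils::write.table(sample_sheet, ss, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    og_wide <- data.frame(Orthogroup = ogs, stringsAsFactors = FALSE)
    for (sp in species) {
      members <- og_map[og_map$species == sp, ]
      cell <- vapply(ogs, function(og)
        paste(members$gene[members$orthogroup == og], collapse = ", "), "")
      og_wide[[sp]] <- cell
    }
    ogp <- file.path(dir, "Orthogroups.tsv")
    utils::write.table(og_wide, ogp, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    lp <- file.path(dir, "lengths.tsv")
    utils::write.table(data.frame(gene = names(lengths),
                                  length = unname(lengths)),
                       lp, sep = "\t", row.names = FALSE, quote = FALSE)
    tp <- file.path(dir, "truth.csv")
    utils::write.csv(data.frame(orthogroup = ogs,
                                fold_change = unname(fold_changes[ogs])),
                     tp, row.names = FALSE, quote = FALSE)
    out$paths <- c(paths, sample_sheet = ss, orthogroups = ogp,
                   lengths = lp, truth = tp)
  }
  out
}

#' Simulate mini-genomes with implanted promoter motif instances
#'
#' Builds random-background contigs carrying annotated genes on both
#' strands, each with a dedicated 1 kb upstream window into which the
#' requested number of non-overlapping motif instances (degenerate
#' positions resolved at random) is implanted at recorded offsets.
#' With `g_free = TRUE` the background alphabet excludes G, making
#' spurious matches of a CGG/CCG-anchored consensus impossible, so
#' recovered counts equal implanted counts exactly.
#'
#' @param seed root seed.
#' @param n_contigs,genes_per_contig genome layout.
#' @param upstream promoter window length in bp (default 1000).
#' @param gene_length gene body length in bp.
#' @param motif IUPAC motif string or [parse_motif()] object.
#' @param implants integer vector of instances to implant per gene,
#'   recycled over genes (default `c(0, 1, 2, 3)`).
#' @param g_free draw background from the G-free alphabet A/C/T?
#' @param species species tag for the family map.
#' @param families family labels recycled over genes.
#' @param dir optional output directory (`genome.fa`, `annotation.gff3`,
#'   `family_map.tsv`, `truth.csv`).
#' @return list with `genome` (named character), `genes` (gene-model data
#'   frame), `family_map`, `truth` (list per gene: implanted 0-based
#'   `offsets` within the promoter and the realised `instances`), and
#'   optional `paths`.
#' @export
simulate_genome_with_motifs <- function(seed = 1L, n_contigs = 2L,
                                        genes_per_contig = 4L,
                                        upstream = 1000L, gene_length = 900L,
                                        motif = "CGGN{11}CCG",
                                        implants = c(0L, 1L, 2L, 3L),
                                        g_free = FALSE,
                                        species = "synthetic_sp",
                                        families = c("TDH", "HXK", "ENO",
                                                     "PYK", "GPM", "PDC"),
                                        dir = NULL) {
  if (is.character(motif)) motif <- parse_motif(motif)
  m <- motif$length
  stopifnot(n_contigs >= 1L, genes_per_contig >= 1L, upstream >= m)
  set.seed(substream_seed(seed, "genome_motifs"))
  alphabet <- if (g_free) c("A", "C", "T") else c("A", "C", "G", "T")
  bg <- function(n) paste(sample(alphabet, n, replace = TRUE), collapse = "")
  realise <- function() paste(vapply(motif$base_sets, function(s)
    s[sample.int(length(s), 1L)], ""), collapse = "")

  n_genes <- n_contigs * genes_per_contig
  implants <- rep_len(as.integer(implants), n_genes)
  if (any(implants * m > upstream))
    stopf("requested implants exceed the %d bp window capacity", upstream)

  genome <- character(0); genes <- list(); truth <- list()
  gi <- 0L
  for (ci in seq_len(n_contigs)) {
    contig <- sprintf("ctg%02d", ci)
    seq_parts <- character(0); pos <- 0L
    for (gj in seq_len(genes_per_contig)) {
      gi <- gi + 1L
      gene <- sprintf("g%03d", gi)
      strand <- if (gi %% 2L == 1L) "+" else "-"
      k <- implants[gi]
      prom <- bg(upstream)
      offs <- integer(0); inst <- character(0)
      if (k > 0L) {
        chunk <- upstream %/% k
        if (chunk < m)
          stopf("gene %s: %d implants do not fit non-overlapping in %d bp",
                gene, k, upstream)
        for (i in seq_len(k)) {
          o <- (i - 1L) * chunk + sample.int(chunk - m + 1L, 1L) - 1L
          s <- realise()
          substr(prom, o + 1L, o + m) <- s
          offs <- c(offs, o); inst <- c(inst, s)
        }
      }
      body <- bg(gene_length)
      if (strand == "+") {
        block <- paste0(prom, body, bg(100L))
        start <- pos + upstream + 1L
      } else {
        block <- paste0(bg(100L), body, revcomp(prom))
        start <- pos + 100L + 1L
      }
      end <- start + gene_length - 1L
      seq_parts <- c(seq_parts, block)
      pos <- pos + nchar(block)
      genes[[gene]] <- data.frame(gene = gene, contig = contig,
                                  start = start, end = end, strand = strand,
                                  stringsAsFactors = FALSE)
      truth[[gene]] <- list(offsets = offs, instances = inst,
                            implanted = k)
    }
    genome[contig] <- paste(seq_parts, collapse = "")
  }
  genes <- do.call(rbind, c(genes, list(make.row.names = FALSE)))
  family_map <- data.frame(gene = genes$gene,
                           family = rep_len(families, nrow(genes)),
                           species = species, stringsAsFactors = FALSE)
  out <- list(genome = genome, genes = genes, family_map = family_map,
              motif = motif,
              truth = list(genes = truth, g_free = g_free,
                           upstream = upstream))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "genome.fa")
    writeLines(as.vector(rbind(paste0(">", names(genome)),
                               unname(genome))), fa)
    gff <- file.path(dir, "annotation.gff3")
    lines <- c("##gff-version 3")
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      lines <- c(lines,
        sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                g$contig, g$start, g$end, g$strand, g$gene),
        sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                g$contig, g$start, g$end, g$strand, g$gene, g$gene),
        sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s.t1",
                g$contig, g$start, g$end, g$strand, g$gene, g$gene))
    }
    writeLines(lines, gff)
    fm <- file.path(dir, "family_map.tsv")
    utils::write.table(family_map, fm, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    tr <- file.path(dir, "truth.csv")
    utils::write.csv(data.frame(
      gene = genes$gene,
      implanted = vapply(truth[genes$gene], `[[`, 0L, "implanted"),
      offsets = vapply(truth[genes$gene], function(t)
        paste(t$offsets, collapse = ";"), "")),
      tr, row.names = FALSE, quote = FALSE)
    out$paths <- c(genome = fa, annotation = gff, family_map = fm,
                   truth = tr)
  }
  out
}
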