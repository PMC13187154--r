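write_counts_file <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("HTSeq-style count files parse with summary rows set aside", {
  f <- write_counts_file(c("g1\t3", "g2\t0", "g3\t12", "__no_feature\t100"))
  ct <- read_counts(f, sample_id = "s1", species = "spA")
  expect_equal(length(ct$counts), 3L)
  expect_equal(unname(ct$counts["g3"]), 12)
  expect_equal(unname(ct$summary["__no_feature"]), 100)

  expect_warning(read_counts(write_counts_file(character(0))), "empty")
  expect_error(read_counts(write_counts_file(c("g1\t3", "g1\t4"))),
               "duplicated gene id.*line 2")
  expect_error(read_counts(write_counts_file(c("g1\t3", "g2\t-1"))),
               "negative count on line 2")
  expect_error(read_counts(write_counts_file(c("g1\tx"))), "non-numeric")
  expect_warning(read_counts(write_counts_file(c("g1\t3.5"))), "fractional")
})

test_that("simulator count files round-trip through the reader", {
  dir <- tempfile(); sim <- simulate_expression(seed = 81, n_orthogroups = 10,
                                                dir = dir)
  for (id in names(sim$counts)[1:3]) {
    ct <- read_counts(file.path(dir, paste0(id, ".counts.tsv")),
                      sample_id = id, species = sim$counts[[id]]$species)
    expect_identical(ct$counts, sim$counts[[id]]$counts)
    expect_identical(ct$summary, sim$counts[[id]]$summary)
  }
  og <- read_orthogroups(file.path(dir, "Orthogroups.tsv"))
  expect_equal(og[order(og$species, og$gene), c("orthogroup", "species", "gene")],
               sim$og_map[order(sim$og_map$species, sim$og_map$gene), ],
               ignore_attr = TRUE)
  expect_equal(read_lengths(file.path(dir, "lengths.tsv")), sim$lengths)
})

test_that("gene lengths come out of GFF3 by span or exon union", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\tx\tgene\t101\t200\t.\t+\t.\tID=gA",
    "c1\tx\tmRNA\t101\t200\t.\t+\t.\tID=gA.t1;Parent=gA",
    "c1\tx\texon\t101\t150\t.\t+\t.\tParent=gA.t1",
    "c1\tx\texon\t141\t200\t.\t+\t.\tParent=gA.t1",
    "c2\tx\tgene\t1\t500\t.\t-\t.\tID=gB",
    "c2\tx\tmRNA\t1\t500\t.\t-\t.\tID=gB.t1;Parent=gB",
    "c2\tx\texon\t1\t100\t.\t-\t.\tParent=gB.t1",
    "c2\tx\texon\t301\t500\t.\t-\t.\tParent=gB.t1"), gff)
  span <- lengths_from_gff(gff, "gene_span")
  expect_equal(span[["gA"]], 100)
  expect_equal(span[["gB"]], 500)
  uni <- lengths_from_gff(gff, "exon_union")
  expect_equal(uni[["gA"]], 100)  # overlapping 101-150 and 141-200
  expect_equal(uni[["gB"]], 300)
})

test_that("exon-union lengths match a brute-force base-set oracle", {
  set.seed(82)
  lines <- "##gff-version 3"
  truth <- numeric(0)
  for (g in sprintf("g%02d", 1:8)) {
    n_ex <- sample(1:4, 1)
    starts <- sort(sample(1:900, n_ex))
    ends <- pmin(starts + sample(10:120, n_ex, replace = TRUE), 1000)
    lines <- c(lines,
               sprintf("c1\tx\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                       min(starts), max(ends), g),
               sprintf("c1\tx\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.t;Parent=%s",
                       min(starts), max(ends), g, g),
               sprintf("c1\tx\texon\t%d\t%d\t.\t+\t.\tParent=%s.t",
                       starts, ends, g))
    truth[g] <- length(unique(unlist(mapply(seq, starts, ends,
                                            SIMPLIFY = FALSE))))
  }
  gff <- tempfile(fileext = ".gff3"); writeLines(lines, gff)
  expect_equal(lengths_from_gff(gff, "exon_union")[names(truth)], truth)
})

test_that("orthogroup aggregation sums counts and lengths per species", {
  og_map <- data.frame(orthogroup = "OG1", species = "spA",
                       gene = c("a1", "a2"))
  ct <- structure(list(sample_id = "s1", species = "spA",
                       counts = c(a1 = 3, a2 = 7), summary = numeric(0)),
                  class = "gene_counts")
  agg <- aggregate_orthogroups(ct, c(a1 = 100, a2 = 300), og_map)
  expect_equal(agg$count, 10)
  expect_equal(agg$length, 400)
  # an orthogroup with no members in a species: count 0, undefined length
  og2 <- rbind(og_map, data.frame(orthogroup = "OG2", species = "spB",
                                  gene = "b1"))
  agg2 <- aggregate_orthogroups(ct, c(a1 = 100, a2 = 300, b1 = 50), og2)
  expect_equal(agg2$count[agg2$orthogroup == "OG2"], 0)
  expect_true(is.na(agg2$length[agg2$orthogroup == "OG2"]))
  expect_error(aggregate_orthogroups(ct, c(a1 = 100), og_map),
               "missing from the length table")
})

test_that("aggregation equals the naive per-gene loop oracle", {
  set.seed(83)
  for (i in 1:10) {
    inst <- random_expression_instance()
    agg <- aggregate_orthogroups(inst$counts, inst$lengths, inst$og_map)
    ref <- aggregate_oracle(inst$counts, inst$lengths, inst$og_map)
    agg <- agg[order(agg$orthogroup, agg$sample), ]
    ref <- ref[order(ref$orthogroup, ref$sample), ]
    expect_identical(agg$count, ref$count)
    expect_identical(unname(agg$length), unname(ref$length))
  }
})

test_that("TPM is conserved at one million per sample", {
  base <- data.frame(orthogroup = c("OG1", "OG2"), sample = "s1",
                     species = "spA", count = c(5, 5), length = c(100, 100))
  expect_equal(compute_tpm(base)$tpm, c(5e5, 5e5))
  single <- base[1, ]
  expect_equal(compute_tpm(single)$tpm, 1e6)
  set.seed(84)
  inst <- random_expression_instance(n_og = 12, n_species = 3)
  tpm <- compute_tpm(aggregate_orthogroups(inst$counts, inst$lengths,
                                           inst$og_map))
  sums <- tapply(tpm$tpm, tpm$sample, sum, na.rm = TRUE)
  expect_true(all(abs(sums - 1e6) <= 1e-6 * 1e6))
  # direct-formula oracle
  s1 <- tpm[tpm$sample == names(sums)[1] & !is.na(tpm$tpm), ]
  rate <- s1$count / s1$length
  expect_equal(s1$tpm, rate / sum(rate) * 1e6, tolerance = 1e-12)
  zero <- base; zero$count <- 0
  expect_error(compute_tpm(zero), "all counts are zero")
})

test_that("splitting a count file and summing after read changes nothing", {
  dir <- tempfile()
  sim <- simulate_expression(seed = 85, n_orthogroups = 8, dir = dir)
  id <- sim$sample_sheet$sample[1]
  f <- file.path(dir, paste0(id, ".counts.tsv"))
  lines <- readLines(f)
  gene_lines <- lines[!startsWith(lines, "__")]
  half <- seq_len(length(gene_lines) %/% 2)
  f1 <- write_counts_file(gene_lines[half])
  f2 <- write_counts_file(gene_lines[-half])
  a <- read_counts(f1, "x", "spA"); b <- read_counts(f2, "x", "spA")
  merged <- c(a$counts, b$counts)
  whole <- read_counts(f, id, "spA")
  expect_identical(merged[names(whole$counts)], whole$counts)
})

test_that("reference comparisons match the closed-form Welch oracle", {
  set.seed(86)
  mk_expr <- function(vals, sp) {
    do.call(rbind, lapply(seq_along(vals), function(i)
      data.frame(orthogroup = "OG1", sample = sprintf("%s_r%d", sp, i),
                 species = sp, tpm = vals[i])))
  }
  ref_v <- rnorm(4, 100, 10); oth_v <- rnorm(4, 160, 20)
  expr <- rbind(mk_expr(ref_v, "refsp"), mk_expr(oth_v, "othsp"))
  out <- compare_to_reference(expr, "refsp")
  w <- welch_oracle(log2(oth_v + 1), log2(ref_v + 1))
  expect_equal(out$t, w$t, tolerance = 1e-10)
  expect_equal(out$p_value, w$p, tolerance = 1e-10)
  expect_equal(out$log2fc, log2((mean(oth_v) + 1) / (mean(ref_v) + 1)),
               tolerance = 1e-12)
  # identical constant replicate vectors: no change, p = 1
  same <- rbind(mk_expr(c(4, 4, 4, 4), "refsp"), mk_expr(c(4, 4, 4, 4), "othsp"))
  out2 <- compare_to_reference(same, "refsp")
  expect_equal(out2$log2fc, 0)
  expect_equal(out2$p_value, 1)
})

test_that("underreplicated comparisons are skipped with a message", {
  expr <- data.frame(orthogroup = "OG1",
                     sample = c("r1", "r2", "o1"),
                     species = c("refsp", "refsp", "othsp"),
                     tpm = c(10, 12, 30))
  expect_error(expect_message(compare_to_reference(expr, "refsp"), "skipped"),
               "no comparisons")
})

test_that("planted fold changes are detected and rank near the top", {
  hit_p <- 0L; hit_rank <- 0L; n_planted <- 0L
  for (s in 1:10) {
    sim <- simulate_expression(seed = 900 + s, n_orthogroups = 60, n_de = 6)
    tpm <- compute_tpm(aggregate_orthogroups(sim$counts, sim$lengths,
                                             sim$og_map))
    cmp <- compare_to_reference(tpm, "Sat_mendoncae")
    cmp <- cmp[cmp$species == "Sat_dispora", ]
    planted <- sim$truth$de_orthogroups
    thr <- quantile(abs(cmp$log2fc), 0.9)
    n_planted <- n_planted + length(planted)
    hit_p <- hit_p + sum(cmp$p_value[cmp$orthogroup %in% planted] < 0.05)
    hit_rank <- hit_rank + sum(abs(cmp$log2fc[cmp$orthogroup %in% planted]) >= thr)
  }
  expect_gte(hit_p / n_planted, 0.9)
  expect_gte(hit_rank / n_planted, 0.9)
})
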