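# Neighborhood extraction, homology grouping, styles, collapsing, spacing,
# guide tree and homolog sampling.

test_that("gene spacing follows the start-minus-end-minus-one convention", {
  g <- function(start, end, contig = "c1")
    list(contig_id = contig, genome_id = "G", start = start, end = end)
  expect_equal(gene_spacing(g(10, 100), g(101, 200)), 0L)    # abutting
  expect_equal(gene_spacing(g(10, 100), g(121, 200)), 20L)
  expect_equal(gene_spacing(g(10, 100), g(91, 200)), -10L)   # overlap
  expect_error(gene_spacing(g(10, 100), g(121, 200, contig = "c2")),
               "different contigs")
  expect_error(gene_spacing(g(121, 200), g(10, 100)), "upstream")
})

test_that("proximity is same-contig, same-strand, gap at most 5 kb inclusive", {
  g <- function(start, end, strand = "+", contig = "c1")
    list(genome_id = "G", contig_id = contig, strand = strand,
         start = start, end = end)
  expect_true(is_nearby(g(1, 100), g(5001, 5200)))       # gap 4900
  expect_false(is_nearby(g(1, 100), g(201, 400, "-")))   # opposite strand
  expect_true(is_nearby(g(1, 100), g(5101, 5300)))       # gap 5000, inclusive
  expect_false(is_nearby(g(1, 100), g(5102, 5300)))      # gap 5001
  expect_true(is_nearby(g(1, 100), g(50, 200)))          # overlap -> 0
  expect_false(is_nearby(g(1, 100), g(200, 300, contig = "c2")))
})

test_that("neighborhood extraction clips at contig ends and mirrors minus anchors", {
  withr::with_seed(71, {
    s <- replicate(3, rand_protein(40))
  })
  d <- tempfile()
  write_toy_genomes(d, list(list(id = "GN", genes = list(
    gLeft = toy_gene(s[1], 100, strand = "+"),
    gMid = toy_gene(s[2], 1000, strand = "-"),
    gRight = toy_gene(s[3], 2000, strand = "+")))))
  db <- load_genomes(file.path(d, "GN.faa"), file.path(d, "GN.gff"),
                     file.path(d, "metadata.tsv"))
  # anchor at the contig edge: one-sided neighborhood, no error
  row <- extract_neighborhood("gLeft", db, window_bp = 10000L)
  expect_equal(nrow(row$genes), 3L)
  expect_equal(row$genes[gene_id == "gLeft", offset], 0L)
  # window 0: only genes overlapping the anchor itself
  row0 <- extract_neighborhood("gMid", db, window_bp = 0L)
  expect_equal(row0$genes$gene_id, "gMid")
  # minus-strand anchor: upstream-in-genome neighbors appear to the right
  rowm <- extract_neighborhood("gMid", db)
  expect_equal(rowm$genes[gene_id == "gMid", offset], 0L)
  expect_gt(rowm$genes[gene_id == "gLeft", offset], 0)
  expect_lt(rowm$genes[gene_id == "gRight", offset], 0)
  expect_equal(rowm$genes[gene_id == "gMid", rel_strand], "+")
  expect_error(extract_neighborhood("nope", db), "anchor gene")
})

test_that("mirroring the genome and re-extracting yields the identical row", {
  withr::with_seed(72, s <- replicate(3, rand_protein(30)))
  mk <- function(flip) {
    d <- tempfile()
    L <- 5000L
    coords <- list(c(100L, 300L), c(600L, 900L), c(1500L, 1800L))
    strands <- c("+", "-", "+")
    genes <- list()
    for (i in 1:3) {
      st <- coords[[i]][1]; en <- coords[[i]][2]; str <- strands[i]
      if (flip) { tmp <- st; st <- L - en + 1L; en <- L - tmp + 1L
                  str <- if (str == "+") "-" else "+" }
      genes[[sprintf("g%d", i)]] <- toy_gene(s[i], st, en, strand = str)
    }
    write_toy_genomes(d, list(list(id = "GM", genes = genes)))
    load_genomes(file.path(d, "GM.faa"), file.path(d, "GM.gff"),
                 file.path(d, "metadata.tsv"))
  }
  r1 <- extract_neighborhood("g2", mk(FALSE))
  r2 <- extract_neighborhood("g2", mk(TRUE))
  cols <- c("gene_id", "rel_start", "rel_end", "rel_strand", "offset")
  expect_equal(r1$genes[, cols, with = FALSE], r2$genes[, cols, with = FALSE])
})

test_that("homology grouping is single linkage at 50% mutual coverage", {
  withr::with_seed(73, {
    core <- rand_protein(100)
    filler1 <- rand_protein(100)
    filler2 <- rand_protein(100)
    a <- paste0(core, filler1)              # 200 aa: core + tail1
    b <- core                               # 100 aa: core only
    cc <- paste0(filler1, filler2)          # 200 aa: tail1 + tail2
    unrel <- rand_protein(150)
  })
  # identical proteins group together
  g0 <- group_by_homology(c("x", "y"), c(core, core))
  expect_equal(g0$group[1], g0$group[2])
  # a<->b share the core (>=50% of both); b<->cc share nothing; a<->cc share
  # tail1 = 50% of each: chain a-b, a-cc links everything (single linkage)
  g <- group_by_homology(c("a", "b", "cc", "u"), c(a, b, cc, unrel))
  expect_equal(uniqueN(g$group[1:3]), 1L)
  expect_false(g$group[4] %in% g$group[1:3])
  # 40% mutual coverage does not link
  withr::with_seed(74, {
    core40 <- rand_protein(40)
    p1 <- paste0(core40, rand_protein(60))
    p2 <- paste0(rand_protein(60), core40)
  })
  g2 <- group_by_homology(c("p1", "p2"), c(p1, p2))
  expect_equal(uniqueN(g2$group), 2L)
})

test_that("grouping agrees with an independent connected-components oracle", {
  skip_if_not_installed("igraph")
  withr::with_seed(75, {
    roots <- replicate(4, rand_protein(80))
    seqs <- unlist(lapply(roots, function(r)
      vapply(1:3, function(k) mutate_seq(r, sample(0:12, 1)), character(1))))
  })
  ids <- sprintf("p%02d", seq_along(seqs))
  g <- group_by_homology(ids, seqs)
  # oracle: explicit link list from the DP oracle, igraph components
  links <- data.table()
  for (i in seq_along(seqs)) for (j in seq_len(i - 1)) {
    pa <- oracle_align(seqs[j], seqs[i], score_only = FALSE)
    if (score(pa) <= 0) next
    covj <- 100 * width(pattern(pa)) / nchar(seqs[j])
    covi <- 100 * width(subject(pa)) / nchar(seqs[i])
    if (covj >= 50 && covi >= 50)
      links <- rbind(links, data.table(a = ids[j], b = ids[i]))
  }
  gr <- igraph::graph_from_data_frame(links, directed = FALSE,
                                      vertices = ids)
  comp <- igraph::components(gr)$membership[g$protein_id]
  expect_equal(uniqueN(paste(g$group, comp)), uniqueN(g$group))
  expect_equal(uniqueN(comp), uniqueN(g$group))
})

test_that("style allocation: white query, 33 cyclic styles, gray singletons", {
  # 34 multi-member groups + query group + 3 singletons
  groups <- data.table(
    protein_id = sprintf("p%03d", 1:(2 * 35 + 3)),
    group = c(rep(1:35, each = 2), 36:38))
  st <- assign_styles(groups, query_group = 1L)
  expect_equal(st[group == 1, kind], "query")
  styled <- st[kind == "styled"]
  expect_equal(nrow(styled), 34L)
  expect_equal(max(styled$style_index), 34L)
  # capacity of distinct non-query styles is 11 colors x 3 hatch states
  expect_equal(uniqueN(styled[, .(color_index, hatch)]), 33L)
  # style 34 reuses style 1's color and hatch
  s1 <- styled[style_index == 1]; s34 <- styled[style_index == 34]
  expect_equal(s34$color_index, s1$color_index)
  expect_equal(s34$hatch, s1$hatch)
  expect_true(all(st[kind == "gray", is.na(style_index)]))
  # 2 multi-member groups + query -> white + 2 distinct styles
  st2 <- assign_styles(data.table(protein_id = sprintf("q%d", 1:5),
                                  group = c(1L, 2L, 2L, 3L, 3L)),
                       query_group = 1L)
  expect_equal(sort(st2$kind), c("query", "styled", "styled"))
  expect_equal(uniqueN(st2[kind == "styled", style_index]), 2L)
})

test_that("collapsing merges only same-species same-cluster hits and keeps all genomes", {
  x <- shared_small_db()
  db <- x$db
  q <- db$clusters[, .N, by = rep_id][order(-N)][1, rep_id]
  hits <- search_direct(q, db)
  # per-genome gene-level rows for collapsing: expand hits to genomes
  per_g <- prokbrowse:::hits_per_genome(hits, db)
  rows <- merge(hits, per_g[, .(protein_id, subject_genome_id = genome_id)],
                by.x = "subject_id", by.y = "protein_id",
                allow.cartesian = TRUE, sort = FALSE)
  rows[, subject_genome_id := subject_genome_id.y]
  rows[, c("subject_genome_id.x", "subject_genome_id.y") := NULL]
  coll <- collapse_by_species(rows, db)
  # no (species, cluster) pair appears twice
  expect_equal(anyDuplicated(coll[, .(species, cluster_rep)]), 0L)
  # uncollapsing recovers every original genome
  expect_setequal(unlist(strsplit(coll$collapsed_genome_ids, ",")),
                  unique(rows$subject_genome_id))
  # rows never merge across species or clusters: each collapsed row's
  # genomes all share the row's species
  sp <- setNames(db$genomes$species, db$genomes$assembly_id)
  for (i in seq_len(nrow(coll))) {
    gids <- strsplit(coll$collapsed_genome_ids[i], ",")[[1]]
    expect_true(all(sp[gids] == coll$species[i]))
  }
  # without a cluster table collapsing is disabled with a warning
  db0 <- prokbrowse:::new_gxdb(db$name, db$genomes, db$genes, db$proteins)
  expect_warning(un <- collapse_by_species(rows, db0), "disabled")
  expect_equal(nrow(un), nrow(rows))
})

test_that("guide tree is midpoint rooted with the best homolog as first leaf", {
  x <- shared_small_db()
  db <- x$db
  q <- db$clusters[, .N, by = rep_id][order(-N)][1, rep_id]
  hits <- head(search_direct(q, db), 8)
  gt <- build_guide_tree(hits, db)
  expect_equal(gt$leaf_order[1], hits$subject_id[1])
  expect_setequal(gt$leaf_order, hits$subject_id)
  # midpoint property: the max root-to-leaf distance is minimal over all
  # possible root placements (exhaustive edge oracle below)
  tr <- gt$tree
  dm <- ape::dist.nodes(tr)
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  achieved <- max(dm[root, 1:ntip])
  expect_lte(achieved, min_possible_root_height(tr) + 1e-9)
})

test_that("two-leaf trees balance the root and midpoint matches the oracle on random trees", {
  # 2 leaves, branch lengths 0.1/0.3 before rooting -> 0.2/0.2 after
  tr2 <- phangorn::midpoint(ape::read.tree(text = "(A:0.1,B:0.3);"))
  dm2 <- ape::dist.nodes(tr2)
  expect_equal(unname(dm2[3, 1]), 0.2)
  expect_equal(unname(dm2[3, 2]), 0.2)
  withr::with_seed(76, {
    for (i in 1:50) {
      tr <- ape::rtree(sample(4:12, 1))
      tr <- ape::unroot(tr)
      rooted <- phangorn::midpoint(tr)
      dm <- ape::dist.nodes(rooted)
      ntip <- length(rooted$tip.label)
      achieved <- max(dm[ntip + 1L, 1:ntip])
      expect_lte(achieved, min_possible_root_height(tr) + 1e-9)
    }
  })
})

test_that("homolog sampling modes honor the cap, the seed and eligibility", {
  withr::with_seed(77, {
    hits <- data.table(subject_id = sprintf("s%03d", 1:500),
                       rank = 1:500,
                       score_ratio = runif(500, 0.05, 1))
  })
  top <- sample_homologs(hits, "top", n_max = 200)
  expect_equal(top$rank, 1:200)
  r1 <- sample_homologs(hits, "random_all", n_max = 50, seed = 9)
  r2 <- sample_homologs(hits, "random_all", n_max = 50, seed = 9)
  r3 <- sample_homologs(hits, "random_all", n_max = 50, seed = 10)
  expect_equal(r1, r2)
  expect_false(identical(r1$subject_id, r3$subject_id))
  good <- sample_homologs(hits, "random_good", n_max = 1000, seed = 1)
  expect_true(all(good$score_ratio >= 0.3))
  expect_equal(nrow(good), sum(hits$score_ratio >= 0.3))  # all eligible
  expect_error(sample_homologs(hits, "bogus"))
})
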