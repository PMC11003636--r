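# Presence/absence comparison of two proteins' homologs and the
# rank-threshold-optimized Fisher statistic.

# build a minimal database skeleton plus synthetic per-genome hit tables
# directly (optimal_threshold and genome_pairs operate on hits + db)
mock_db <- function(n) {
  ids <- sprintf("G%03d", seq_len(n))
  genomes <- rbindlist(lapply(ids, toy_meta_row))
  genomes[, assembly_id := ids]
  genomes[, `:=`(n_genes = 10L, n_protein_coding = 10L)]
  genes <- data.table(
    gene_id = paste0(ids, "_g1"), genome_id = ids, contig_id = "c1",
    start = 1L, end = 300L, strand = "+", is_protein_coding = TRUE,
    annotation = "x", locus_tag = NA_character_,
    protein_id = paste0("P_", ids))
  proteins <- data.table(protein_id = paste0("P_", ids),
                         sequence = strrep("M", 100), length = 100L)
  prokbrowse:::new_gxdb("mock", genomes, genes, proteins)
}

# synthetic classified hit table hitting the given genomes at given ranks
mock_hits <- function(db, genomes, ranks = seq_along(genomes),
                      ratios = 0.9) {
  data.table(query_id = "q", subject_id = paste0("P_", genomes),
             raw_score = 100L, bit_score = 50 - ranks,
             e_value = 1e-10, pct_identity = 90, query_cov = 95,
             subject_cov = 95, qstart = 1L, qend = 90L, sstart = 1L,
             send = 90L, matches = 81L, align_cols = 90L,
             rank = ranks, subject_genome_id = genomes,
             score_ratio = rep_len(ratios, length(genomes)),
             is_homolog = TRUE, is_potential_ortholog = TRUE,
             is_good_homolog = rep_len(ratios, length(genomes)) >= 0.3,
             is_high_coverage_ortholog = TRUE)
}

test_that("identical 5-of-100 hit lists give the closed-form hypergeometric P", {
  db <- mock_db(100)
  g5 <- db$genomes$assembly_id[1:5]
  hits <- mock_hits(db, g5, ranks = 1:5)
  scan <- optimal_threshold(hits, hits, db)
  row5 <- scan$scan[k == 5]
  expect_equal(unlist(row5[, .(n11, n10, n01, n00)], use.names = FALSE),
               c(5L, 0L, 0L, 95L))
  expect_equal(row5$p, 1 / choose(100, 5))
  expect_equal(scan$p_min, 1 / choose(100, 5))
  expect_equal(scan$p_corrected,
               min(1, scan$p_min * scan$bonferroni_factor))
  # one-sided Fisher on the same table agrees
  ft <- fisher.test(matrix(c(5, 0, 0, 95), 2), alternative = "greater")
  expect_equal(row5$p, ft$p.value, tolerance = 1e-12)
})

test_that("disjoint or empty hit lists carry no enrichment evidence", {
  db <- mock_db(40)
  ha <- mock_hits(db, db$genomes$assembly_id[1:10])
  hb <- mock_hits(db, db$genomes$assembly_id[31:40])
  expect_equal(optimal_threshold(ha, hb, db)$p_corrected, 1)
  none <- ha[0]
  expect_equal(optimal_threshold(ha, none, db)$p_corrected, 1)
  expect_equal(nrow(genome_pairs(none, none, db)), 0L)
})

test_that("optimal_threshold equals a brute-force scan on random instances", {
  db <- mock_db(40)
  ids <- db$genomes$assembly_id
  withr::with_seed(81, {
    for (trial in 1:100) {
      na_ <- sample(3:25, 1); nb <- sample(3:25, 1)
      ga <- sample(ids, na_); gb <- sample(ids, nb)
      ha <- mock_hits(db, ga, ranks = sample(seq_len(na_)))
      hb <- mock_hits(db, gb, ranks = sample(seq_len(nb)))
      scan <- optimal_threshold(ha, hb, db)
      # independent brute force: every rank 1..n_genomes via fisher.test
      ra <- setNames(ha$rank, ha$subject_genome_id)[ids]
      rb <- setNames(hb$rank, hb$subject_genome_id)[ids]
      ps <- vapply(1:40, function(k) {
        pa <- !is.na(ra) & ra <= k
        pb <- !is.na(rb) & rb <= k
        fisher.test(table(factor(pa, c(TRUE, FALSE)),
                          factor(pb, c(TRUE, FALSE))),
                    alternative = "greater")$p.value
      }, numeric(1))
      expect_equal(scan$p_min, min(ps), tolerance = 1e-9)
      # the reported k* attains the global minimum
      expect_equal(ps[scan$k_star], min(ps), tolerance = 1e-9)
      # and no candidate smaller than k* does better or ties
      smaller <- scan$scan[k < scan$k_star, p]
      if (length(smaller)) expect_gt(min(smaller), scan$p_min)
    }
  })
})

test_that("the corrected P controls type-I error on independent pairs", {
  db <- mock_db(200)
  ids <- db$genomes$assembly_id
  withr::with_seed(82, {
    rejected <- vapply(1:500, function(i) {
      ga <- sample(ids, rbinom(1, 200, 0.3))
      gb <- sample(ids, rbinom(1, 200, 0.3))
      if (length(ga) == 0 || length(gb) == 0) return(FALSE)
      ha <- mock_hits(db, ga, ranks = sample(seq_along(ga)))
      hb <- mock_hits(db, gb, ranks = sample(seq_along(gb)))
      optimal_threshold(ha, hb, db)$p_corrected < 0.05
    }, logical(1))
  })
  expect_lte(mean(rejected), 0.05)
})

test_that("an implanted co-occurring pair is recovered with tiny corrected P", {
  db <- mock_db(60)
  ids <- db$genomes$assembly_id
  withr::with_seed(83, both <- sample(ids, 30))
  ha <- mock_hits(db, both, ranks = sample(1:30))
  hb <- mock_hits(db, both, ranks = sample(1:30))
  scan <- optimal_threshold(ha, hb, db)
  expect_lt(scan$p_corrected, 1e-6)
  # invariance under genome relabeling
  perm <- setNames(sample(ids), ids)
  relabel <- function(h) {
    h2 <- copy(h)
    h2[, subject_genome_id := perm[subject_genome_id]]
    h2[, subject_id := paste0("P_", subject_genome_id)]
    h2
  }
  scan2 <- optimal_threshold(relabel(ha), relabel(hb), db)
  expect_equal(scan2$p_min, scan$p_min)
  expect_equal(scan2$k_star, scan$k_star)
})

test_that("genome pairs mark absent sides, fusion and proximity correctly", {
  x <- shared_small_db()
  db <- x$db
  truth <- x$truth
  fam_of <- unlist(truth$gene_family)
  pid_for <- function(fam, genome) {
    g <- names(fam_of)[fam_of == fam & startsWith(names(fam_of), genome)]
    db$genes[gene_id %in% g, protein_id][1]
  }
  ga <- truth$implant$both[1]
  ha <- search_direct(pid_for("PAIRA", ga), db)
  hb <- search_direct(pid_for("PAIRB", ga), db)
  pairs <- genome_pairs(ha, hb, db)
  # every genome in the table carries at least one side; the absent side
  # is NA (rendered below zero in the plot)
  expect_true(all(!is.na(pairs$ratio_a) | !is.na(pairs$ratio_b)))
  onesided <- pairs[is.na(ratio_a) | is.na(ratio_b)]
  expect_true(all(!onesided$nearby) && all(!onesided$fused))
  # implanted nearby genomes are flagged nearby (both strands and <= 5 kb
  # by construction)
  near <- intersect(truth$implant$nearby, pairs$genome_id)
  expect_true(all(pairs[genome_id %in% near & !is.na(ratio_a) &
                          !is.na(ratio_b), nearby]))
  # a fusion: same best protein for both queries
  fused <- genome_pairs(ha, ha, db)
  expect_true(all(fused$fused))
  # mismatched databases are rejected
  expect_error(genome_pairs(mock_hits(mock_db(3),
                                      mock_db(3)$genomes$assembly_id),
                            hb, db), "not in this database")
})

test_that("co-occurrence summary counts, monotonicity and taxa tables", {
  x <- shared_small_db()
  db <- x$db
  truth <- x$truth
  fam_of <- unlist(truth$gene_family)
  pid_of <- function(fam) {
    g <- names(fam_of)[fam_of == fam][1]
    db$genes[gene_id == g, protein_id]
  }
  ha <- search_direct(pid_of("PAIRA"), db)
  hb <- search_direct(pid_of("PAIRB"), db)
  s <- cooccur_summary(ha, hb, db, level = "phylum")
  cnt <- s$counts
  expect_equal(cnt[, both + a_only + b_only + neither],
               rep(n_genomes(db), 2))
  # good-homolog counts never exceed all-homolog counts componentwise
  expect_lte(cnt[set == "good", both], cnt[set == "all", both])
  # proximity taxa are a subset of co-occurrence taxa
  expect_true(all(s$taxa_nearby %in% s$taxa_both))
  # the SVG plot writes a parseable file
  f <- tempfile(fileext = ".svg")
  render_cooccur_svg(s$pairs, f)
  expect_true(file.exists(f))
  expect_no_error(xml2::read_xml(f))
})
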