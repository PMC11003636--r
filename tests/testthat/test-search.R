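# Direct and clustered search, hit classification, the sensitivity
# schedule and the split-align-merge workflow contract.

test_that("sensitivity schedule reproduces all five breakpoints", {
  expect_equal(sensitivity_for_length(150), 7.5)
  expect_equal(sensitivity_for_length(151), 7.0)
  expect_equal(sensitivity_for_length(250), 7.0)
  expect_equal(sensitivity_for_length(350), 6.25)
  expect_equal(sensitivity_for_length(400), 6.0)
  expect_equal(sensitivity_for_length(650), 6.0)
  expect_equal(sensitivity_for_length(1000), 5.7)
  expect_error(sensitivity_for_length(0))
})

test_that("hit classification respects its inclusive boundaries", {
  cfg <- search_config(n_genomes = 100, db_len = 1e6)
  mk <- function(idy, qcov, scov, bits) data.table(
    query_id = "q", subject_id = "s", raw_score = 1L, bit_score = bits,
    e_value = 1e-10, pct_identity = idy, query_cov = qcov,
    subject_cov = scov, qstart = 1L, qend = 10L, sstart = 1L, send = 10L,
    matches = 5L, align_cols = 10L, rank = 1L)
  h <- classify_hits(mk(30, 50, 40, 30), query_self_bits = 100, cfg)
  expect_true(h$is_homolog)
  expect_true(h$is_potential_ortholog)   # exactly at 30% / 50%
  expect_true(h$is_good_homolog)         # ratio exactly 0.30
  expect_false(h$is_high_coverage_ortholog)
  h <- classify_hits(mk(29.9, 50, 40, 29), query_self_bits = 100, cfg)
  expect_false(h$is_potential_ortholog)
  expect_false(h$is_good_homolog)        # ratio 0.29
  h <- classify_hits(mk(45, 95, 95, 60), query_self_bits = 100, cfg)
  expect_true(all(h$is_homolog, h$is_potential_ortholog, h$is_good_homolog,
                  h$is_high_coverage_ortholog))
})

test_that("direct search caps hits at the genome count and keeps top scores", {
  x <- shared_small_db()
  db <- x$db
  cfg <- search_config(db)
  q <- db$proteins$protein_id[1]
  hits <- search_direct(q, db, cfg)
  expect_lte(nrow(hits), n_genomes(db))
  expect_true(all(hits$e_value <= cfg$e_max))
  expect_equal(hits$rank, seq_len(nrow(hits)))
  # truncation equals sort-then-head on the unfiltered hit list
  full <- batch_search(db$proteins[protein_id == q, sequence],
                       db$proteins$protein_id, db$proteins$sequence,
                       params = align_params(db_len = cfg$db_len))
  oracle <- head(full[e_value <= cfg$e_max], cfg$max_hits)
  expect_equal(hits$subject_id, oracle$subject_id)
  # a foreign query with no homologs yields an empty table
  withr::with_seed(61, none <- search_direct(rand_protein(100), db, cfg))
  expect_equal(nrow(none), 0L)
})

test_that("very short queries fall back to exhaustive alignment, not empty results", {
  x <- shared_small_db()
  db <- x$db
  short <- "MKL"
  hits <- search_direct(short, db)
  expect_s3_class(hits, "data.table")  # no error; prefilter bypassed
})

test_that("clustered search expands a representative's whole cluster and caps candidates", {
  x <- shared_small_db()
  db <- x$db
  cfg <- search_config(db)
  expect_equal(cfg$candidate_cap, 200L)  # small db: cap is the 200 floor
  big <- db$clusters[, .N, by = rep_id][order(-N)][1, rep_id]
  hits <- search_clustered(big, db, cfg)
  members <- db$clusters[rep_id == big, member_id]
  expect_true(all(members %in% hits$subject_id))
  # clustered results always satisfy the E-value gate and rank contract
  expect_true(all(hits$e_value <= cfg$e_max))
  expect_equal(hits$rank, seq_len(nrow(hits)))
})

test_that("clustered search requires a cluster table", {
  x <- shared_small_db()
  db <- x$db
  db$clusters <- NULL
  expect_error(search_clustered(db$proteins$protein_id[1], db), "cluster")
})

test_that("search results are invariant to database insertion order", {
  x <- shared_small_db()
  db <- x$db
  q <- db$proteins$protein_id[3]
  h1 <- search_direct(q, db)
  db2 <- prokbrowse:::new_gxdb(db$name, db$genomes,
                               db$genes[rev(seq_len(nrow(db$genes)))],
                               db$proteins[rev(seq_len(nrow(db$proteins)))],
                               db$clusters)
  h2 <- search_direct(q, db2)
  expect_equal(h2$subject_id, h1$subject_id)
  expect_equal(h2$bit_score, h1$bit_score)
})

test_that("candidate splitting preserves the multiset and merging restores order", {
  cand <- data.table(id = sprintf("c%03d", 1:100), score = 100:1)
  parts <- split_candidates(cand, 10L)
  expect_length(parts, 10L)
  expect_true(all(vapply(parts, nrow, integer(1)) == 10L))
  expect_equal(rbindlist(parts), cand)
  # uneven split still partitions
  parts2 <- split_candidates(cand[1:97], 10L)
  expect_equal(sum(vapply(parts2, nrow, integer(1))), 97L)
  expect_equal(rbindlist(parts2), cand[1:97])
  # merge of internally sorted parts is globally sorted, truncated to
  # n_genomes entries
  withr::with_seed(62, {
    hits <- data.table(query_id = "q", subject_id = sprintf("s%02d", 1:20),
                       bit_score = runif(20, 20, 90))
  })
  hits[, e_value := evalue(bit_score, 100, 1e5)]
  parts3 <- split_candidates(hits, 4L)
  merged <- merge_hit_parts(parts3, n_keep = 10L)
  expect_equal(nrow(merged), 10L)
  expect_equal(merged$subject_id,
               hits[order(-bit_score, e_value, subject_id)][1:10, subject_id])
})

test_that("the external-engine adapter errors when no engine is configured", {
  x <- shared_small_db()
  expect_error(parallel_engine_search("MKLV", x$db, engine = NULL),
               "capability")
  expect_error(parallel_engine_search("MKLV", x$db,
                                      engine = "/no/such/engine"),
               "capability")
})
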