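# Evaluation harness: rank-binned miss rates of a test search method against
# a reference method, with the standard filters (E <= 1e-5, rank <= half the
# number of genomes, ortholog subsets).

#' Rank-binned miss-rate curve of a test method versus a reference
#'
#' The reference universe is the reference hits with E <= `e_cap` and rank
#' <= `rank_cap` (half the number of genomes by default elsewhere, since
#' hits further down the list are unlikely to be orthologs), optionally
#' restricted to potential orthologs (>= 30% identity, >= 50% query
#' coverage) or additionally to score ratio >= 0.3. A reference hit is
#' missed iff its (query, subject) pair is absent from the test results;
#' scores are never compared, because different engines use different score
#' scales. Hits are binned by reference rank in windows of `bin` ranks.
#'
#' @param reference_hits,test_hits Hit tables (possibly concatenated over
#'   queries) with `query_id`, `subject_id`, `rank`, `e_value`, and, for
#'   the ortholog subsets, `pct_identity`, `query_cov`, `score_ratio`.
#' @param rank_cap Keep reference hits with rank <= `rank_cap` (>= 1).
#' @param e_cap Reference E-value cutoff.
#' @param bin Bin width in ranks.
#' @param subset `"all"`, `"ortholog"` or `"ortholog_scoreratio"`.
#' @return List with `curve` (per-bin `data.table`: `bin_start`, `bin_end`,
#'   `n_reference`, `n_missed`, `miss_rate`), `overall` miss rate, and the
#'   filter descriptor.
#' @export
miss_rate_by_rank <- function(reference_hits, test_hits, rank_cap,
                              e_cap = 1e-5, bin = 50L,
                              subset = c("all", "ortholog",
                                         "ortholog_scoreratio")) {
  subset <- match.arg(subset)
  if (rank_cap < 1) stop("rank_cap must be >= 1")
  ref <- as.data.table(reference_hits)
  ref <- ref[e_value <= e_cap & rank <= rank_cap]
  if (subset %in% c("ortholog", "ortholog_scoreratio"))
    ref <- ref[pct_identity >= 30 & query_cov >= 50]
  if (subset == "ortholog_scoreratio")
    ref <- ref[score_ratio >= 0.3]
  test <- as.data.table(test_hits)
  test_keys <- if (nrow(test)) paste(test$query_id, test$subject_id)
               else character()
  ref[, missed := !(paste(query_id, subject_id) %in% test_keys)]
  ref[, bin_idx := ceiling(rank / bin)]
  curve <- ref[, .(n_reference = .N, n_missed = sum(missed)),
               by = bin_idx]
  setorder(curve, bin_idx)
  curve[, `:=`(bin_start = (bin_idx - 1L) * as.integer(bin) + 1L,
               bin_end = bin_idx * as.integer(bin),
               miss_rate = n_missed / n_reference)]
  curve <- curve[, .(bin_start, bin_end, n_reference, n_missed, miss_rate)]
  list(curve = curve,
       overall = if (nrow(ref)) sum(ref$missed) / nrow(ref) else NaN,
       n_reference = nrow(ref), n_missed = sum(ref$missed),
       subset = subset, rank_cap = rank_cap, e_cap = e_cap, bin = bin)
}

#' Draw a random benchmark query set from a database
#'
#' Uniform seeded sample of protein ids without replacement, of size
#' `min(n, number of distinct proteins)`.
#'
#' @param db A `gxdb` object.
#' @param n Number of queries requested.
#' @param seed Integer seed.
#' @return Character vector of protein ids.
#' @export
benchmark_queries <- function(db, n = 1000L, seed = 1L) {
  ids <- db$proteins$protein_id
  if (length(ids) == 0L) stop("database has no proteins")
  withr::with_seed(seed, sample(ids, min(n, length(ids))))
}
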