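# Greedy incremental clustering of a protein set at 70% identity and 90%
# both-way coverage, producing representative-based clusters for the
# clustered search and for same-species collapsing in the neighborhood view.

#' Greedy incremental protein clustering
#'
#' Proteins are processed in length-descending order (ties broken by id);
#' each protein joins the first existing cluster — in cluster-creation
#' order — whose representative it aligns to with at least `min_identity`
#' percent identity and an alignment covering at least `min_cov_both`
#' percent of *both* sequences, otherwise it founds a new cluster. The
#' representative is therefore always the longest member. Identity uses the
#' package-wide convention (matches over alignment columns including gaps),
#' applied uniformly even though some greedy clustering tools measure
#' identity over the shorter sequence.
#'
#' Candidate clusters are prescreened with the k-mer prefilter (at least
#' `min_words` shared 4-mers — two by default, which contract-satisfying
#' pairs exceed by an order of magnitude) plus a length bound implied by
#' the contract itself (a representative longer than
#' `member_length / (min_identity * min_cov_both)` cannot satisfy it). The
#' membership contract of the output is verified independently by
#' [verify_clusters()].
#'
#' @param proteins `data.frame` with `protein_id` and `sequence`
#'   (deduplicated).
#' @param min_identity,min_cov_both Thresholds in percent, each in (0, 100].
#' @param params [align_params()] object.
#' @param min_words Minimum shared 4-mers for the candidate prescreen.
#' @return `data.table` with `cluster_id`, `rep_id`, `member_id`,
#'   `identity`, `cov_member`, `cov_rep`; the representative is listed
#'   first in each cluster (with identity/coverages 100).
#' @export
greedy_cluster <- function(proteins, min_identity = 70, min_cov_both = 90,
                           params = align_params(), min_words = 2L) {
  if (min_identity <= 0 || min_identity > 100 ||
      min_cov_both <= 0 || min_cov_both > 100)
    stop("thresholds must be in (0, 100]")
  p <- as.data.table(proteins)[, .(protein_id, sequence)]
  if (anyDuplicated(p$protein_id)) stop("duplicate protein ids")
  p[, len := nchar(sequence)]
  setorder(p, -len, protein_id)
  res <- .greedy_cluster_core(toupper(p$sequence), substitution_matrix(),
                              params$gap_open, params$gap_extend,
                              min_identity, min_cov_both, 4L,
                              as.integer(min_words))
  out <- data.table(cluster_id = res$cluster,
                    rep_id = p$protein_id[res$rep_row[res$cluster]],
                    member_id = p$protein_id,
                    identity = res$identity, cov_member = res$cov_member,
                    cov_rep = res$cov_rep)
  out[, is_rep := member_id == rep_id]
  setorder(out, cluster_id, -is_rep, -identity, member_id)
  out[, is_rep := NULL]
  out[]
}

#' Verify the cluster membership contract
#'
#' Re-aligns every member to its representative and reports any violation of
#' the identity / both-way coverage contract. The report is empty on any
#' valid clustering (in particular on [greedy_cluster()] output).
#'
#' @param clusters Cluster table as returned by [greedy_cluster()].
#' @param proteins `data.frame` with `protein_id` and `sequence` covering
#'   every id in `clusters`.
#' @param min_identity,min_cov_both Contract thresholds in percent.
#' @param params [align_params()] object.
#' @return `data.table` of violations (`rep_id`, `member_id`, `rule`,
#'   `value`); zero rows when the contract holds.
#' @export
verify_clusters <- function(clusters, proteins, min_identity = 70,
                            min_cov_both = 90, params = align_params()) {
  cl <- as.data.table(clusters)
  p <- as.data.table(proteins)
  dangling <- setdiff(unique(c(cl$rep_id, cl$member_id)), p$protein_id)
  if (length(dangling))
    stop("cluster table references unknown protein(s): ",
         paste(head(dangling, 5), collapse = ", "))
  seqs <- setNames(p$sequence, p$protein_id)
  submat <- substitution_matrix()
  bad <- list()
  for (r in unique(cl$rep_id)) {
    members <- setdiff(cl[rep_id == r, member_id], r)
    if (!length(members)) next
    for (k in seq_along(members)) {
      # member as query, mirroring the direction greedy_cluster admits on
      a <- .sw_batch(seqs[[members[k]]], seqs[[r]], submat,
                     params$gap_open, params$gap_extend)
      if (a$raw_score[1] <= 0) {
        bad[[length(bad) + 1L]] <- data.table(
          rep_id = r, member_id = members[k], rule = "no_alignment",
          value = 0)
        next
      }
      identity <- 100 * a$matches[1] / a$align_cols[1]
      cov_mem <- 100 * (a$qend[1] - a$qstart[1] + 1) / nchar(seqs[[members[k]]])
      cov_rep <- 100 * (a$send[1] - a$sstart[1] + 1) / nchar(seqs[[r]])
      if (identity < min_identity)
        bad[[length(bad) + 1L]] <- data.table(
          rep_id = r, member_id = members[k], rule = "identity",
          value = identity)
      if (cov_mem < min_cov_both)
        bad[[length(bad) + 1L]] <- data.table(
          rep_id = r, member_id = members[k], rule = "cov_member",
          value = cov_mem)
      if (cov_rep < min_cov_both)
        bad[[length(bad) + 1L]] <- data.table(
          rep_id = r, member_id = members[k], rule = "cov_rep",
          value = cov_rep)
    }
  }
  if (length(bad)) rbindlist(bad)
  else data.table(rep_id = character(), member_id = character(),
                  rule = character(), value = numeric())
}

#' Cluster a database's proteins and attach the cluster table
#'
#' @param db A `gxdb` object.
#' @param min_identity,min_cov_both Contract thresholds in percent.
#' @param params [align_params()] object.
#' @return The database with `db$clusters` populated.
#' @export
cluster_database <- function(db, min_identity = 70, min_cov_both = 90,
                             params = align_params()) {
  db$clusters <- greedy_cluster(db$proteins, min_identity, min_cov_both,
                                params)
  db
}
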