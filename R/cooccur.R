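# Comparing the presence and absence of two proteins' homologs across
# genomes: per-genome best score ratios, proximity and fusion flags,
# co-occurrence counts, and the rank-threshold-optimized Fisher statistic.

#' Are two genes encoded nearby?
#'
#' True iff the genes are on the same genome, contig and strand and the gap
#' between their nearest ends is at most `max_dist` bp (5 kb by default,
#' inclusive); overlapping genes count as distance 0.
#'
#' @param gene_a,gene_b One-row gene records (`genome_id`, `contig_id`,
#'   `strand`, `start`, `end`).
#' @param max_dist Maximum separation in bp.
#' @return Logical flag.
#' @export
is_nearby <- function(gene_a, gene_b, max_dist = 5000L) {
  if (gene_a$genome_id != gene_b$genome_id ||
      gene_a$contig_id != gene_b$contig_id ||
      gene_a$strand != gene_b$strand) return(FALSE)
  gap <- max(0L, max(gene_a$start, gene_b$start) -
               min(gene_a$end, gene_b$end) - 1L)
  gap <= max_dist
}

# minimum same-strand/same-contig gap between any A-gene and B-gene of one
# genome; Inf when no same-contig same-strand pair exists
min_pair_gap <- function(genes_a, genes_b) {
  best <- Inf
  for (i in seq_len(nrow(genes_a))) for (j in seq_len(nrow(genes_b))) {
    if (genes_a$contig_id[i] != genes_b$contig_id[j] ||
        genes_a$strand[i] != genes_b$strand[j]) next
    gap <- max(0L, max(genes_a$start[i], genes_b$start[j]) -
                 min(genes_a$end[i], genes_b$end[j]) - 1L)
    best <- min(best, gap)
  }
  best
}

#' Per-genome presence pattern of two proteins' homologs
#'
#' One row per genome with at least one hit of either protein: the score
#' ratio of the best hit on each side (`NA` marks absence, rendered below
#' zero in the plot), a `nearby` flag (best homolog genes of the two
#' queries within 5 kb on the same strand), and a `fused` flag (the same
#' subject protein is the best hit for both queries).
#'
#' @param hits_a,hits_b Classified hit tables from the same database.
#' @param db The `gxdb` both searches ran against.
#' @param max_dist Proximity threshold in bp.
#' @return `data.table` with per-genome ratios, flags and lineage.
#' @export
genome_pairs <- function(hits_a, hits_b, db, max_dist = 5000L) {
  known <- db$genomes$assembly_id
  claimed <- c(as.data.table(hits_a)$subject_genome_id,
               as.data.table(hits_b)$subject_genome_id)
  bad <- setdiff(claimed[!is.na(claimed)], known)
  if (length(bad))
    stop("hits reference genomes not in this database: ",
         paste(head(bad, 5), collapse = ", "))
  ga <- hits_per_genome(hits_a, db)
  gb <- hits_per_genome(hits_b, db)
  m <- merge(ga[, .(genome_id, protein_a = protein_id, ratio_a = score_ratio,
                    rank_a = rank)],
             gb[, .(genome_id, protein_b = protein_id, ratio_b = score_ratio,
                    rank_b = rank)],
             by = "genome_id", all = TRUE)
  if (nrow(m) == 0L) {
    m[, `:=`(nearby = logical(), fused = logical())]
    return(m[])
  }
  m[, fused := !is.na(protein_a) & !is.na(protein_b) &
      protein_a == protein_b]
  m[, nearby := FALSE]
  both <- which(!is.na(m$ratio_a) & !is.na(m$ratio_b))
  for (i in both) {
    genes_a <- db$genes[genome_id == m$genome_id[i] &
                          protein_id == m$protein_a[i]]
    genes_b <- db$genes[genome_id == m$genome_id[i] &
                          protein_id == m$protein_b[i]]
    m$nearby[i] <- min_pair_gap(genes_a, genes_b) <= max_dist
  }
  lin <- db$genomes[, c("assembly_id", TAX_LEVELS), with = FALSE]
  m <- merge(m, lin, by.x = "genome_id", by.y = "assembly_id", sort = TRUE)
  m[]
}

#' Optimal shared rank threshold for co-occurrence
#'
#' Scans candidate rank thresholds k (the distinct ranks at which either
#' hit list gains a genome, capped at the number of genomes); at each k a
#' genome is "present" for a protein iff its best hit for that protein has
#' rank <= k. For each k a one-sided (enrichment) Fisher exact P is
#' computed from the 2x2 table over *all* database genomes — including
#' genomes with no homolog of either protein — via the hypergeometric tail.
#' The reported threshold minimizes P (ties broken toward the smallest k)
#' and the minimal P is Bonferroni-corrected by the number of candidate
#' thresholds considered.
#'
#' @param hits_a,hits_b Classified hit tables from the same database.
#' @param db The `gxdb` both searches ran against.
#' @return List (`threshold_scan`): `scan` table (k and 2x2 counts and P),
#'   `k_star`, `p_min`, `bonferroni_factor`, `p_corrected`.
#' @export
optimal_threshold <- function(hits_a, hits_b, db) {
  ga <- hits_per_genome(hits_a, db)
  gb <- hits_per_genome(hits_b, db)
  N <- n_genomes(db)
  empty <- list(scan = data.table(k = integer(), n11 = integer(),
                                  n10 = integer(), n01 = integer(),
                                  n00 = integer(), p = numeric()),
                k_star = NA_integer_, p_min = NA_real_,
                bonferroni_factor = 0L, p_corrected = 1)
  if (nrow(ga) == 0L || nrow(gb) == 0L) {
    class(empty) <- "threshold_scan"
    return(empty)
  }
  rank_a <- setNames(ga$rank, ga$genome_id)
  rank_b <- setNames(gb$rank, gb$genome_id)
  ks <- sort(unique(c(rank_a, rank_b)))
  ks <- ks[ks <= N]
  if (length(ks) == 0L) {
    class(empty) <- "threshold_scan"
    return(empty)
  }
  genomes <- db$genomes$assembly_id
  ra <- rank_a[genomes]  # NA = absent
  rb <- rank_b[genomes]
  scan <- rbindlist(lapply(ks, function(k) {
    pa <- !is.na(ra) & ra <= k
    pb <- !is.na(rb) & rb <= k
    n11 <- sum(pa & pb); n10 <- sum(pa & !pb)
    n01 <- sum(!pa & pb); n00 <- sum(!pa & !pb)
    # one-sided Fisher (enrichment) = hypergeometric upper tail
    p <- stats::phyper(n11 - 1, n11 + n10, n01 + n00, n11 + n01,
                       lower.tail = FALSE)
    data.table(k = k, n11 = n11, n10 = n10, n01 = n01, n00 = n00, p = p)
  }))
  i_star <- which.min(scan$p)  # ties -> smallest k (ks are sorted)
  out <- list(scan = scan, k_star = scan$k[i_star], p_min = scan$p[i_star],
              bonferroni_factor = nrow(scan),
              p_corrected = min(1, scan$p[i_star] * nrow(scan)))
  class(out) <- "threshold_scan"
  out
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf(
    "<threshold_scan>: %d candidate thresholds; k* = %s, P = %.3g, corrected P = %.3g\n",
    x$bonferroni_factor, as.character(x$k_star), x$p_min, x$p_corrected))
  invisible(x)
}

#' Co-occurrence summary of two proteins' homologs
#'
#' Counts of genomes with both / A only / B only / neither, computed twice
#' (for all homologs and for "good" homologs at score ratio >= 0.3), the
#' per-genome proximity flags, the optimal rank threshold statistic, and
#' taxa tables at a chosen rank listing taxa containing both genes and taxa
#' containing them in proximity.
#'
#' @param hits_a,hits_b Classified hit tables from the same database.
#' @param db The `gxdb` both searches ran against.
#' @param level Taxonomic rank for the taxa tables.
#' @param max_dist Proximity threshold in bp.
#' @return List with `pairs` (the [genome_pairs()] table), `counts` (a
#'   `data.table` with rows `all` and `good`), `threshold` (the
#'   [optimal_threshold()] result), `taxa_both`, `taxa_nearby`.
#' @export
cooccur_summary <- function(hits_a, hits_b, db, level = "phylum",
                            max_dist = 5000L) {
  pairs <- genome_pairs(hits_a, hits_b, db, max_dist = max_dist)
  count_block <- function(pa, pb, label) {
    data.table(set = label,
               both = sum(pa & pb), a_only = sum(pa & !pb),
               b_only = sum(!pa & pb),
               neither = n_genomes(db) - sum(pa | pb))
  }
  pa <- !is.na(pairs$ratio_a); pb <- !is.na(pairs$ratio_b)
  ga <- pa & pairs$ratio_a >= 0.3; gb <- pb & pairs$ratio_b >= 0.3
  ga[is.na(ga)] <- FALSE; gb[is.na(gb)] <- FALSE
  counts <- rbind(count_block(pa, pb, "all"), count_block(ga, gb, "good"))
  both_tax <- pairs[pa & pb, sort(unique(get(level)))]
  near_tax <- pairs[pa & pb & nearby == TRUE, sort(unique(get(level)))]
  list(pairs = pairs, counts = counts,
       threshold = optimal_threshold(hits_a, hits_b, db),
       taxa_both = both_tax, taxa_nearby = near_tax, level = level)
}

#' Render the presence/absence scatter as SVG
#'
#' Each point is a genome with a homolog of either protein; axes are the
#' best-hit score ratios. Genomes with the two homologs encoded nearby are
#' green, fusion candidates (same best protein for both queries) blue, the
#' rest black; genomes with a homolog of only one protein are drawn in a
#' gray band below zero on the absent axis.
#'
#' @param pairs Output of [genome_pairs()].
#' @param file Output SVG path.
#' @param size Canvas size in px.
#' @return The path, invisibly.
#' @export
render_cooccur_svg <- function(pairs, file, size = 420) {
  pad <- 50; band <- 30
  sc <- function(v) pad + v * (size - 2 * pad)            # ratio -> x
  scy <- function(v) (size - pad) - v * (size - 2 * pad)  # ratio -> y
  pt <- function(x, y, col)
    sprintf('<circle cx="%.1f" cy="%.1f" r="3" fill="%s" fill-opacity="0.7"/>',
            x, y, col)
  body <- character()
  body <- c(body, sprintf(
    '<rect x="%d" y="%.1f" width="%d" height="%d" fill="#dddddd"/>',
    0L, size - pad, size, band),
    sprintf('<rect x="%d" y="%d" width="%d" height="%d" fill="#dddddd"/>',
            0L, 0L, band, size))
  for (i in seq_len(nrow(pairs))) {
    ra <- pairs$ratio_a[i]; rb <- pairs$ratio_b[i]
    col <- if (isTRUE(pairs$fused[i])) "#1f4fff"
           else if (isTRUE(pairs$nearby[i])) "#1a9640" else "#000000"
    x <- if (is.na(ra)) band / 2 else sc(ra)
    y <- if (is.na(rb)) size - pad + band / 2 else scy(rb)
    body <- c(body, pt(x, y, col))
  }
  svg <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    size, size), body, "</svg>")
  dir.create(dirname(file), showWarnings = FALSE, recursive = TRUE)
  writeLines(svg, file)
  invisible(file)
}
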