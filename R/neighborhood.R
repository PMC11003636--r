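# Gene-neighborhood view: flanking genes for top homologs, homology color
# groups, same-species collapsing, gene spacings, and a guide tree that
# orders the rows with the closest homologs first.

#' Extract the gene neighborhood around an anchor gene
#'
#' All genes on the anchor's contig overlapping
#' `[anchor_start - window, anchor_end + window]` (clipped at contig ends),
#' with signed offsets from the anchor start, oriented so the anchor points
#' rightward: when the anchor is on the minus strand all coordinates are
#' mirrored and strands flipped.
#'
#' @param anchor_gene_id Gene id present in the database.
#' @param db A `gxdb` object.
#' @param window_bp Flank size in bp on each side (default 10 kb).
#' @return List (`neighborhood_row`) with the anchor gene id, genome,
#'   contig and a `genes` table (`rel_start`, `rel_end`, `rel_strand`,
#'   `offset`), sorted by offset; the anchor sits at offset 0.
#' @export
extract_neighborhood <- function(anchor_gene_id, db, window_bp = 10000L) {
  anchor <- db$genes[gene_id == anchor_gene_id]
  if (nrow(anchor) == 0L)
    stop("anchor gene not in database: ", anchor_gene_id)
  g <- db$genes[genome_id == anchor$genome_id &
                  contig_id == anchor$contig_id &
                  end >= anchor$start - window_bp &
                  start <= anchor$end + window_bp]
  if (anchor$strand == "+") {
    g[, `:=`(rel_start = start - anchor$start,
             rel_end = end - anchor$start,
             rel_strand = strand)]
  } else {
    g[, `:=`(rel_start = anchor$end - end,
             rel_end = anchor$end - start,
             rel_strand = ifelse(strand == "+", "-", "+"))]
  }
  g[, offset := rel_start]
  setorder(g, offset, gene_id)
  structure(list(anchor_gene_id = anchor_gene_id,
                 genome_id = anchor$genome_id,
                 contig_id = anchor$contig_id,
                 genes = g[]),
            class = "neighborhood_row")
}

#' Group visible proteins by homology
#'
#' All-vs-all alignment of the visible proteins; pairs whose alignment
#' covers at least `min_cov_both` percent of *both* sequences are linked,
#' and groups are the connected components of these links (single linkage),
#' built by processing pairs in bit-score-descending order so the grouping
#' is deterministic.
#'
#' @param protein_ids,sequences Parallel vectors of the visible proteins.
#' @param min_cov_both Mutual-coverage threshold in percent (default 50).
#' @param params [align_params()] object.
#' @return `data.table` with `protein_id` and integer `group` (groups
#'   numbered by first appearance in input order).
#' @export
group_by_homology <- function(protein_ids, sequences, min_cov_both = 50,
                              params = align_params()) {
  n <- length(protein_ids)
  stopifnot(n >= 1, length(sequences) == n)
  submat <- substitution_matrix()
  links <- list()
  for (i in seq_len(max(n - 1L, 0L))) {
    a <- .sw_batch(sequences[i], sequences[(i + 1L):n], submat,
                   params$gap_open, params$gap_extend)
    js <- (i + 1L):n
    ok <- a$raw_score > 0 &
      100 * (a$qend - a$qstart + 1) / nchar(sequences[i]) >= min_cov_both &
      100 * (a$send - a$sstart + 1) / nchar(sequences[js]) >= min_cov_both
    if (any(ok))
      links[[length(links) + 1L]] <- data.table(
        i = i, j = js[ok], bits = bit_score(a$raw_score[ok], params))
  }
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (length(links)) {
    links <- rbindlist(links)
    setorder(links, -bits, i, j)
    for (r in seq_len(nrow(links))) {
      ri <- find(links$i[r]); rj <- find(links$j[r])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  group <- match(root, unique(root))
  data.table(protein_id = protein_ids, group = group)
}

#' Assign color/hatch styles to homology groups
#'
#' The query's group is white (effectively an extra color). The remaining
#' multi-member groups — in descending size, ties by first appearance —
#' receive styles from a fixed sequence of 11 colors crossed with 3 hatch
#' states (none, hatch1, hatch2), i.e. 33 distinct styles, reused
#' cyclically from style 34 on. Singleton groups are a neutral gray and do
#' not consume a style.
#'
#' @param groups Output of [group_by_homology()].
#' @param query_group Integer group id of the query protein's group.
#' @return `data.table` with `group`, `kind` (query/gray/styled),
#'   `style_index` (1-based, NA unless styled), `color_index` (0-10) and
#'   `hatch` (none/h1/h2).
#' @export
assign_styles <- function(groups, query_group) {
  g <- as.data.table(groups)
  if (nrow(g) == 0L) stop("no groups to style")
  info <- g[, .(size = .N, first_row = min(.I)), by = group]
  info[, kind := ifelse(group == query_group, "query",
                        ifelse(size == 1L, "gray", "styled"))]
  styled <- info[kind == "styled"]
  setorder(styled, -size, first_row)
  styled[, style_index := seq_len(.N)]
  info <- merge(info, styled[, .(group, style_index)], by = "group",
                all.x = TRUE)
  info[, color_index := (style_index - 1L) %% 11L]
  info[, hatch := c("none", "h1", "h2")[((style_index - 1L) %/% 11L) %% 3L
                                        + 1L]]
  setorder(info, group)
  info[, .(group, kind, style_index, color_index, hatch)]
}

#' Collapse same-species near-duplicate homologs
#'
#' Hits that belong to the same species *and* whose subject proteins sit in
#' the same cluster merge into one row represented by the highest-scoring
#' member; the merged genomes are recorded. Hits differing in species or
#' cluster never merge. Without a cluster table collapsing is disabled
#' with a warning.
#'
#' @param hits Classified hit table with `subject_genome_id`.
#' @param db A `gxdb` object with `db$clusters` populated.
#' @return Collapsed hit table with `collapsed_genome_ids` (comma-joined)
#'   and `n_collapsed`.
#' @export
collapse_by_species <- function(hits, db) {
  hits <- as.data.table(hits)
  if (is.null(db$clusters)) {
    warning("no cluster table; collapsing disabled")
    hits[, `:=`(collapsed_genome_ids = subject_genome_id,
                n_collapsed = 1L)]
    return(hits[])
  }
  sp <- db$genomes[, .(assembly_id, species)]
  cl <- db$clusters[, .(member_id, cluster_rep = rep_id)]
  x <- merge(hits, sp, by.x = "subject_genome_id", by.y = "assembly_id",
             all.x = TRUE, sort = FALSE)
  x <- merge(x, cl, by.x = "subject_id", by.y = "member_id", all.x = TRUE,
             sort = FALSE)
  x[is.na(cluster_rep), cluster_rep := subject_id]
  setorder(x, rank)
  out <- x[, {
    best <- .SD[1]
    best$collapsed_genome_ids <- paste(sort(unique(subject_genome_id)),
                                       collapse = ",")
    best$n_collapsed <- .N
    best
  }, by = .(species, cluster_rep)]
  setorder(out, rank)
  out[]
}

#' Spacing in nucleotides between two genes on one contig
#'
#' `start(g2) - end(g1) - 1`: 0 means abutting genes, negative values an
#' overlap of that many bp.
#'
#' @param g1,g2 One-row gene records on the same contig, `g1` upstream of
#'   `g2` by start coordinate.
#' @return Integer spacing in bp.
#' @export
gene_spacing <- function(g1, g2) {
  if (g1$contig_id != g2$contig_id ||
      (!is.null(g1$genome_id) && g1$genome_id != g2$genome_id))
    stop("genes are on different contigs")
  if (g1$start > g2$start) stop("g1 must be upstream of g2 (by start)")
  as.integer(g2$start - g1$end - 1L)
}

#' Build the guide tree ordering neighborhood rows
#'
#' Pairwise distances are `1 - fractional identity` of alignments between
#' the query-similar regions of the homologs (only the part of each
#' sequence matched to the query); a neighbor-joining tree is built, rooted
#' at the midpoint (the point minimizing the maximum root-to-leaf
#' distance), and at each internal node children are ordered by their best
#' descendant bit score so the strongest homolog is the first leaf.
#'
#' @param hits Classified hit table (needs `subject_id`, `sstart`, `send`,
#'   `bit_score`).
#' @param db A `gxdb` object supplying the subject sequences.
#' @param params [align_params()] object.
#' @return List with `tree` (an `ape::phylo`, rooted) and `leaf_order`
#'   (subject ids, best homolog first).
#' @export
build_guide_tree <- function(hits, db, params = align_params()) {
  hits <- as.data.table(hits)
  ids <- hits$subject_id
  n <- length(ids)
  if (n < 2L) return(list(tree = NULL, leaf_order = ids))
  seqs <- db$proteins[match(ids, protein_id), sequence]
  region <- substr(seqs, hits$sstart, hits$send)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  submat <- substitution_matrix()
  for (i in seq_len(n - 1L)) {
    a <- .sw_batch(region[i], region[(i + 1L):n], submat,
                   params$gap_open, params$gap_extend)
    d <- ifelse(a$raw_score > 0, 1 - a$matches / a$align_cols, 1)
    D[i, (i + 1L):n] <- d
    D[(i + 1L):n, i] <- d
  }
  tree <- if (n == 2L) {
    ape::read.tree(text = sprintf("(%s:%f,%s:%f);", ids[1], D[1, 2] / 2,
                                  ids[2], D[1, 2] / 2))
  } else {
    t0 <- ape::nj(stats::as.dist(D))
    t0$edge.length[t0$edge.length < 0] <- 0
    phangorn::midpoint(t0)
  }
  score <- setNames(hits$bit_score, ids)
  ord <- order_children_by_score(tree, score)
  list(tree = ord$tree, leaf_order = ord$leaf_order)
}

# reorder the children of every internal node so the subtree containing the
# highest-scoring leaf comes first; returns a cladewise-valid phylo plus
# the implied leaf order
order_children_by_score <- function(tree, leaf_score) {
  ntip <- length(tree$tip.label)
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])[1]
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  node_best <- function(node) {
    if (node <= ntip) return(leaf_score[[tree$tip.label[node]]])
    max(vapply(tree$edge[kids[[as.character(node)]], 2], node_best,
               numeric(1)))
  }
  new_edges <- integer(0)
  dfs <- function(node) {
    erows <- kids[[as.character(node)]]
    if (is.null(erows)) return(invisible())
    scores <- vapply(tree$edge[erows, 2], node_best, numeric(1))
    for (e in erows[order(-scores)]) {
      new_edges <<- c(new_edges, e)
      dfs(tree$edge[e, 2])
    }
  }
  dfs(root)
  tree$edge <- tree$edge[new_edges, , drop = FALSE]
  if (!is.null(tree$edge.length))
    tree$edge.length <- tree$edge.length[new_edges]
  attr(tree, "order") <- "cladewise"
  tip_order <- tree$edge[tree$edge[, 2] <= ntip, 2]
  list(tree = tree, leaf_order = tree$tip.label[tip_order])
}

#' Sample homologs for display
#'
#' Either the top `n_max` homologs by rank, or a seeded uniform sample
#' without replacement from all homologs or from the "good" homologs
#' (score ratio >= 0.3); at most 200 homologs are shown by default.
#'
#' @param hits Classified hit table.
#' @param mode `"top"`, `"random_all"` or `"random_good"`.
#' @param n_max Maximum homologs to keep.
#' @param seed Seed for the random modes.
#' @return Subset of `hits` (rank order preserved).
#' @export
sample_homologs <- function(hits, mode = c("top", "random_all",
                                           "random_good"),
                            n_max = 200L, seed = 1L) {
  mode <- match.arg(mode)
  hits <- as.data.table(hits)
  if (mode == "top") return(head(hits[order(rank)], n_max))
  eligible <- if (mode == "random_good") hits[score_ratio >= 0.3] else hits
  if (nrow(eligible) <= n_max) return(eligible[order(rank)])
  take <- withr::with_seed(seed, sample(nrow(eligible), n_max))
  eligible[sort(take)][order(rank)]
}

#' Render neighborhood rows as a simple SVG figure
#'
#' One row per homolog: gene arrows colored by homology group (query group
#' white, singletons gray), a homology-extent bar on the anchor, and the
#' taxon label at the right.
#'
#' @param rows List of `neighborhood_row` objects.
#' @param styles Per-protein style table: `protein_id`, `kind`,
#'   `color_index`, `hatch` (join of [group_by_homology()] and
#'   [assign_styles()]).
#' @param db A `gxdb` object (taxon labels).
#' @param file Output SVG path.
#' @param bp_per_px Horizontal scale.
#' @return The path, invisibly.
#' @export
render_neighborhood_svg <- function(rows, styles, db, file,
                                    bp_per_px = 40) {
  palette <- c("#e6194b", "#3cb44b", "#ffe119", "#4363d8", "#f58231",
               "#911eb4", "#46f0f0", "#f032e6", "#bcf60c", "#fabebe",
               "#008080")
  styles <- as.data.table(styles)
  row_h <- 34; mid_w <- 900
  body <- character()
  for (ri in seq_along(rows)) {
    r <- rows[[ri]]
    y <- ri * row_h
    taxon <- db$genomes[assembly_id == r$genome_id, species]
    for (gi in seq_len(nrow(r$genes))) {
      g <- r$genes[gi]
      st <- styles[protein_id == (g$protein_id %||% "")]
      fill <- if (!g$is_protein_coding) "#cccccc"
        else if (nrow(st) == 0L) "#aaaaaa"
        else if (st$kind[1] == "query") "#ffffff"
        else if (st$kind[1] == "gray") "#bbbbbb"
        else palette[st$color_index[1] + 1L]
      x1 <- mid_w / 2 + g$rel_start / bp_per_px
      x2 <- mid_w / 2 + g$rel_end / bp_per_px
      pts <- if (g$rel_strand == "+")
        sprintf("%.1f,%.1f %.1f,%.1f %.1f,%.1f %.1f,%.1f %.1f,%.1f",
                x1, y - 8, x2 - 5, y - 8, x2, y, x2 - 5, y + 8, x1, y + 8)
      else
        sprintf("%.1f,%.1f %.1f,%.1f %.1f,%.1f %.1f,%.1f %.1f,%.1f",
                x2, y - 8, x1 + 5, y - 8, x1, y, x1 + 5, y + 8, x2, y + 8)
      body <- c(body, sprintf(
        '<polygon points="%s" fill="%s" stroke="#333333"/>', pts, fill))
    }
    body <- c(body, sprintf(
      '<text x="%d" y="%.1f" font-size="11">%s</text>',
      mid_w + 10L, y + 4, taxon))
  }
  svg <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    mid_w + 260L, (length(rows) + 1L) * row_h), body, "</svg>")
  dir.create(dirname(file), showWarnings = FALSE, recursive = TRUE)
  writeLines(svg, file)
  invisible(file)
}
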