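# Parse genomes and metadata, deduplicate protein sequences, and persist a
# queryable comparative database (one "main" database plus optional
# order-scoped sub-databases).

TAX_LEVELS <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")

META_COLUMNS <- c("assembly_id", TAX_LEVELS, "is_isolate", "completeness",
                  "contamination", "is_chimeric", "mimag_high_quality",
                  "in_refseq", "is_type_species",
                  "is_species_representative", "in_important_strains",
                  "largest_scaffold_bp")

DB_FORMAT_VERSION <- 1L

#' Load annotated genomes into a comparative database
#'
#' Reads protein FASTA and GFF3 gene coordinates (1-based inclusive, per the
#' GFF3 convention used throughout the package) for a set of assemblies plus
#' a per-assembly metadata TSV, resolves genes to deduplicated protein
#' sequences, and returns a database object. The assembly id of each
#' FASTA/GFF file is its base filename without extension; contig ids are
#' scoped per genome (the global key is (genome_id, contig_id)). CDS
#' features must have a protein sequence in the matching FASTA (keyed by the
#' GFF `ID` attribute); features of other types are retained as non-coding
#' genes for neighborhood display but excluded from all searches.
#'
#' @param fasta_paths,gff_paths Parallel file sets (matched by assembly id).
#' @param metadata Path to a metadata TSV or an equivalent `data.frame`.
#'   Must contain the documented columns; unknown columns are ignored with a
#'   warning; a missing assembly is a hard error.
#' @param name Database name.
#' @param verbose Log a parse report.
#' @return A `gxdb` database object.
#' @export
load_genomes <- function(fasta_paths, gff_paths, metadata,
                         name = "main", verbose = FALSE) {
  fa_ids <- sub("\\.[^.]*$", "", basename(fasta_paths))
  gff_ids <- sub("\\.[^.]*$", "", basename(gff_paths))
  if (!setequal(fa_ids, gff_ids))
    stop("FASTA and GFF3 file sets name different assemblies: ",
         paste(c(setdiff(fa_ids, gff_ids), setdiff(gff_ids, fa_ids)),
               collapse = ", "))
  meta <- if (is.character(metadata)) read_tsv(metadata)
          else as.data.table(metadata)
  missing_cols <- setdiff(META_COLUMNS, names(meta))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(meta), META_COLUMNS)
  if (length(extra)) {
    warning("ignoring unknown metadata column(s): ",
            paste(extra, collapse = ", "))
    meta <- meta[, META_COLUMNS, with = FALSE]
  }
  absent <- setdiff(fa_ids, meta$assembly_id)
  if (length(absent))
    stop("no metadata for assembly: ", paste(absent, collapse = ", "))
  meta <- meta[assembly_id %in% fa_ids]
  for (lv in TAX_LEVELS)
    if (any(is.na(meta[[lv]]) | !nzchar(meta[[lv]])))
      stop("empty taxonomy rank '", lv, "' in metadata")

  gene_list <- list()
  seq_list <- list()
  names(gff_paths) <- gff_ids
  names(fasta_paths) <- fa_ids
  for (aid in sort(fa_ids)) {
    gr <- tryCatch(rtracklayer::import(gff_paths[[aid]], format = "gff3"),
                   error = function(e)
                     stop("malformed GFF3 in ", gff_paths[[aid]], ": ",
                          conditionMessage(e), call. = FALSE))
    mc <- S4Vectors::mcols(gr)
    ids <- as.character(mc$ID)
    if (any(is.na(ids) | !nzchar(ids)))
      stop("GFF3 feature without ID attribute in ", gff_paths[[aid]])
    aa <- Biostrings::readAAStringSet(fasta_paths[[aid]])
    names(aa) <- sub("\\s.*", "", names(aa))
    coding <- as.character(mc$type) == "CDS"
    no_seq <- coding & !(ids %in% names(aa))
    if (any(no_seq))
      stop("CDS gene(s) with no protein FASTA entry in assembly ", aid,
           ": ", paste(head(ids[no_seq], 5), collapse = ", "))
    gdt <- data.table(
      gene_id = ids,
      genome_id = aid,
      contig_id = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      is_protein_coding = coding,
      annotation = if ("product" %in% names(mc))
        as.character(mc$product) else NA_character_,
      locus_tag = if ("locus_tag" %in% names(mc))
        as.character(mc$locus_tag) else NA_character_)
    if (any(gdt$start < 1L)) stop("gene with start < 1 in assembly ", aid)
    gene_list[[aid]] <- gdt
    seq_list[[aid]] <- data.table(gene_id = ids[coding],
                                  sequence = as.character(aa[ids[coding]]))
  }
  genes <- rbindlist(gene_list)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids across assemblies")
  coding_seqs <- rbindlist(seq_list)
  dd <- dedupe_proteins(coding_seqs)
  genes <- merge(genes, dd$mapping, by = "gene_id", all.x = TRUE,
                 sort = FALSE)
  setorder(genes, genome_id, contig_id, start, gene_id)

  meta[, n_genes := genes[, .N, by = genome_id][
    match(meta$assembly_id, genome_id), N]]
  meta[, n_protein_coding := genes[is_protein_coding == TRUE, .N,
                                   by = genome_id][
    match(meta$assembly_id, genome_id), N]]
  for (cc in c("n_genes", "n_protein_coding"))
    meta[is.na(get(cc)), (cc) := 0L]
  setorder(meta, assembly_id)

  db <- new_gxdb(name, meta, genes, dd$proteins)
  if (verbose)
    message(sprintf(
      "loaded %d genomes, %d genes (%d coding), %d distinct proteins",
      nrow(meta), nrow(genes), sum(genes$is_protein_coding),
      nrow(dd$proteins)))
  db
}

#' Deduplicate protein sequences
#'
#' Collapses genes with identical amino-acid sequences onto one protein
#' record each; the protein id is a stable content hash of the sequence so
#' deduplication is deterministic across runs. The database consequently
#' counts distinct sequences, not protein-coding genes.
#'
#' @param genes_with_sequences `data.frame` with `gene_id` and `sequence`.
#' @return List with `proteins` (`protein_id`, `sequence`, `length`) and
#'   `mapping` (`gene_id` -> `protein_id`).
#' @export
dedupe_proteins <- function(genes_with_sequences) {
  gs <- as.data.table(genes_with_sequences)
  if (nrow(gs) == 0L)
    return(list(proteins = data.table(protein_id = character(),
                                      sequence = character(),
                                      length = integer()),
                mapping = data.table(gene_id = character(),
                                     protein_id = character())))
  if (any(is.na(gs$sequence) | !nzchar(gs$sequence)))
    stop("empty protein sequence for gene(s): ",
         paste(head(gs[is.na(sequence) | !nzchar(sequence), gene_id], 5),
               collapse = ", "))
  gs[, sequence := toupper(sequence)]
  gs[, protein_id := hash_sequences(sequence)]
  proteins <- unique(gs[, .(protein_id, sequence)], by = "protein_id")
  proteins[, length := nchar(sequence)]
  setorder(proteins, protein_id)
  list(proteins = proteins[],
       mapping = gs[, .(gene_id, protein_id)])
}

new_gxdb <- function(name, genomes, genes, proteins, clusters = NULL) {
  structure(list(name = name, genomes = genomes, genes = genes,
                 proteins = proteins, clusters = clusters,
                 cache = new.env(parent = emptyenv())),
            class = "gxdb")
}

#' @export
print.gxdb <- function(x, ...) {
  cat(sprintf(
    "<gxdb '%s'>: %d genomes, %d genes, %d distinct proteins%s\n",
    x$name, nrow(x$genomes), nrow(x$genes), nrow(x$proteins),
    if (!is.null(x$clusters))
      sprintf(", %d clusters", length(unique(x$clusters$rep_id))) else ""))
  invisible(x)
}

#' Number of genomes in a database
#' @param db A `gxdb` object.
#' @return Integer genome count.
#' @export
n_genomes <- function(db) nrow(db$genomes)

# total residues across distinct proteins; the effective database length
db_residues <- function(db) sum(db$proteins$length)

# genomes carrying each protein (via the gene table)
protein_genomes <- function(db) {
  db$genes[is_protein_coding == TRUE,
           .(genome_id = unique(genome_id)), by = protein_id]
}

db_tables <- function(db) {
  tabs <- list(genomes = db$genomes, genes = db$genes,
               proteins = db$proteins)
  if (!is.null(db$clusters)) tabs$clusters <- db$clusters
  tabs
}

#' Persist a database to a single text file
#'
#' Writes a versioned single-file container: a header line followed by one
#' TSV section per table. The round trip through [load_database()] is
#' lossless (field-level equality).
#'
#' @param db A `gxdb` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
save_database <- function(db, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tabs <- db_tables(db)
  out <- c(paste("#prokbrowse-db", DB_FORMAT_VERSION, db$name, sep = "\t"))
  for (nm in names(tabs)) {
    tf <- tempfile()
    fwrite(tabs[[nm]], tf, sep = "\t", quote = FALSE, na = "NA",
           eol = "\n", logical01 = FALSE, scipen = 0)
    lines <- readLines(tf)
    unlink(tf)
    out <- c(out, paste("##table", nm, nrow(tabs[[nm]]), sep = "\t"), lines)
  }
  tmp <- paste0(path, ".tmp")
  writeLines(out, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Load a database saved by [save_database()]
#'
#' Refuses on-disk schema versions other than the one this package writes.
#'
#' @param path File written by [save_database()].
#' @return A `gxdb` object.
#' @export
load_database <- function(path) {
  if (!file.exists(path)) stop("no such database file: ", path)
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 3L || hdr[1] != "#prokbrowse-db")
    stop("not a prokbrowse database file: ", path)
  if (as.integer(hdr[2]) != DB_FORMAT_VERSION)
    stop("database schema version ", hdr[2], " not supported (expected ",
         DB_FORMAT_VERSION, "); rebuild the database")
  marks <- grep("^##table\t", lines)
  tabs <- list()
  for (i in seq_along(marks)) {
    info <- strsplit(lines[marks[i]], "\t", fixed = TRUE)[[1]]
    from <- marks[i] + 1L
    to <- if (i < length(marks)) marks[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    tabs[[info[2]]] <- fread(text = paste(block, collapse = "\n"),
                             sep = "\t", header = TRUE, na.strings = "NA",
                             colClasses = DB_SCHEMAS[[info[2]]])
    if (nrow(tabs[[info[2]]]) != as.integer(info[3]))
      stop("corrupt database file: table ", info[2], " row count mismatch")
  }
  new_gxdb(hdr[3], tabs$genomes, tabs$genes, tabs$proteins, tabs$clusters)
}

DB_SCHEMAS <- list(
  genomes = c(assembly_id = "character", domain = "character",
              phylum = "character", class = "character",
              order = "character", family = "character",
              genus = "character", species = "character",
              is_isolate = "logical", completeness = "numeric",
              contamination = "numeric", is_chimeric = "logical",
              mimag_high_quality = "logical", in_refseq = "logical",
              is_type_species = "logical",
              is_species_representative = "logical",
              in_important_strains = "logical",
              largest_scaffold_bp = "integer", n_genes = "integer",
              n_protein_coding = "integer"),
  genes = c(gene_id = "character", genome_id = "character",
            contig_id = "character", start = "integer", end = "integer",
            strand = "character", is_protein_coding = "logical",
            annotation = "character", locus_tag = "character",
            protein_id = "character"),
  proteins = c(protein_id = "character", sequence = "character",
               length = "integer"),
  clusters = c(cluster_id = "integer", rep_id = "character",
               member_id = "character", identity = "numeric",
               cov_member = "numeric", cov_rep = "numeric"))

#' Export the database tables as TSV files
#'
#' @param db A `gxdb` object.
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
export_tables <- function(db, dir) {
  tabs <- db_tables(db)
  paths <- vapply(names(tabs), function(nm) {
    write_tsv(tabs[[nm]], file.path(dir, paste0(nm, ".tsv")))
  }, character(1))
  invisible(paths)
}

#' Build a database from a directory of generated/curated inputs
#'
#' Convenience wrapper: expects `<assembly>.faa` + `<assembly>.gff` pairs
#' and a `metadata.tsv` in `dir` (the layout [simulate_genomes()] emits),
#' applies the genome quality gate, optionally restricts to one taxonomic
#' order, and optionally picks representatives per group.
#'
#' @param dir Input directory.
#' @param name Database name.
#' @param order_name If non-`NULL`, keep only genomes of this order.
#' @param quality_filter Drop genomes failing [passes_quality()] (the
#'   default); when `FALSE` every genome is kept and flagged.
#' @param representatives `NULL` for no selection, otherwise a list with
#'   `rank` ("genus" or "species") and `max_per_group`.
#' @param verbose Log a parse report.
#' @return A `gxdb` object.
#' @export
build_database <- function(dir, name = "main", order_name = NULL,
                           quality_filter = TRUE, representatives = NULL,
                           verbose = FALSE) {
  fa <- sort(list.files(dir, pattern = "\\.faa$", full.names = TRUE))
  gff <- sort(list.files(dir, pattern = "\\.gff$", full.names = TRUE))
  db <- load_genomes(fa, gff, file.path(dir, "metadata.tsv"), name = name,
                     verbose = verbose)
  keep <- db$genomes$assembly_id
  if (!is.null(order_name))
    keep <- intersect(keep, db$genomes[order == order_name, assembly_id])
  if (quality_filter) {
    q <- passes_quality(db$genomes)
    keep <- intersect(keep, q[pass == TRUE, assembly_id])
  }
  if (!is.null(representatives)) {
    picked <- pick_representatives(db$genomes[assembly_id %in% keep],
                                   group_rank = representatives$rank,
                                   max_per_group =
                                     representatives$max_per_group)
    keep <- unlist(picked, use.names = FALSE)
  }
  subset_db(db, keep, name = name)
}

# restrict a database to a genome subset, dropping orphaned proteins
subset_db <- function(db, genome_ids, name = db$name) {
  genomes <- db$genomes[assembly_id %in% genome_ids]
  genes <- db$genes[genome_id %in% genome_ids]
  proteins <- db$proteins[protein_id %in%
                            genes[is_protein_coding == TRUE, protein_id]]
  clusters <- if (!is.null(db$clusters))
    db$clusters[member_id %in% proteins$protein_id] else NULL
  new_gxdb(name, genomes, genes, proteins, clusters)
}
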