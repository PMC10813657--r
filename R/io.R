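#' Read a per-sample eccDNA circle table
#'
#' Reads a TSV produced downstream of a split-read circle caller, with
#' columns chrom, start, end, split_reads and an optional fifth sample_id
#' column. Coordinates are 0-based half-open (BED convention). Lines
#' starting with '#' are ignored. Malformed rows (non-integer coordinates,
#' start >= end, split_reads < 1) reject the whole file with the offending
#' row number.
#'
#' @param path Path to a ".ecc.tsv" file.
#' @param sample_id Sample identifier; defaults to the file name stripped of
#'   its ".ecc.tsv"/".tsv" suffix, overridden by a sample_id column if present.
#' @return A data.frame of eccDNA records (see [ecc_records()]).
#' @export
read_eccdna_table <- function(path, sample_id = NULL) {
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  rows <- lines[keep]
  rownum <- which(keep)
  if (length(rows) == 0L) {
    sid <- if (is.null(sample_id)) sub("(\\.ecc)?\\.tsv$", "", basename(path)) else sample_id
    return(ecc_records(character(), character(), integer(), integer(), integer())[0, ])
  }
  fields <- strsplit(rows, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 4L))
    stop(sprintf("%s: row %d has fewer than 4 columns", path, rownum[which(ncol < 4L)[1]]))
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  sr <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  bad <- which(is.na(start) | is.na(end) | is.na(sr))
  if (length(bad))
    stop(sprintf("%s: row %d has non-integer coordinates or split-read count",
                 path, rownum[bad[1]]))
  bad <- which(start >= end)
  if (length(bad))
    stop(sprintf("%s: row %d has start >= end", path, rownum[bad[1]]))
  bad <- which(sr < 1L)
  if (length(bad))
    stop(sprintf("%s: row %d has split_reads < 1", path, rownum[bad[1]]))
  if (is.null(sample_id))
    sample_id <- sub("(\\.ecc)?\\.tsv$", "", basename(path))
  sid <- rep(sample_id, length(rows))
  has5 <- ncol >= 5L
  sid[has5] <- vapply(fields[has5], `[[`, "", 5L)
  ecc_records(sid, chrom, start, end, sr)
}

#' Write an eccDNA circle table
#'
#' Emits the BED3+1 compatible TSV read back by [read_eccdna_table()].
#'
#' @param records eccDNA record data.frame.
#' @param path Output path.
#' @param with_sample_id Include the sample_id column (default TRUE).
#' @export
write_eccdna_table <- function(records, path, with_sample_id = TRUE) {
  cols <- c("chrom", "start", "end", "split_reads",
            if (with_sample_id) "sample_id")
  utils::write.table(records[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED or GTF
#'
#' All coordinates are normalized to 0-based half-open: BED passes through,
#' GTF (1-based inclusive) has its start decremented by one and its end kept.
#' Only `gene` features are taken from GTF.
#'
#' @param path Path to a BED6 (or BED4) file, or a GTF.
#' @param dialect "bed" or "gtf".
#' @return A gene-model data.frame (see [gene_models()]).
#' @export
read_gene_models <- function(path, dialect = c("bed", "gtf")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            comment.char = "#", stringsAsFactors = FALSE)
    if (ncol(df) < 4L) stop("BED gene file needs at least 4 columns (chrom, start, end, name)")
    strand <- if (ncol(df) >= 6L) df[[6L]] else "."
    gm <- gene_models(gene_id = df[[4L]], symbol = df[[4L]], chrom = df[[1L]],
                      start = df[[2L]], end = df[[3L]], strand = strand)
  } else {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("GTF input requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "gene"]
    if (length(gr) == 0L) stop("no gene features in GTF ", path)
    sym <- if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id
    sym[is.na(sym)] <- gr$gene_id[is.na(sym)]
    gm <- gene_models(gene_id = gr$gene_id, symbol = sym,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))))
  }
  if (any(gm$length <= 0L)) stop("gene with non-positive normalized length")
  gm
}

#' Write gene models as BED6
#' @param genes Gene-model data.frame.
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  utils::write.table(data.frame(genes$chrom, genes$start, genes$end,
                                genes$symbol, 0L, genes$strand),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a chromosomal-fragile-site gene table
#'
#' TSV with columns gene_symbol, cfs_id, chrom, agent (HumCFS style). The
#' agent must be one of aphidicolin, folic acid, BrdU, 5-azacytidine,
#' distamycinA. A `pooled` flag marking membership in the all-agent union
#' category is attached to every row.
#'
#' @param path Path to the TSV (header required).
#' @return A data.frame with columns gene_symbol, cfs_id, chrom, agent, pooled.
#' @export
read_cfs_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE,
                          quote = "")
  need <- c("gene_symbol", "cfs_id", "chrom", "agent")
  if (!all(need %in% names(df)))
    stop("CFS table must have columns ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$agent), CFS_AGENTS)
  if (length(bad)) stop("unknown CFS-inducing agent: ", paste(bad, collapse = ", "))
  df <- df[, need]
  df$pooled <- TRUE
  df
}

#' Read a two-column homolog symbol map
#'
#' HomoloGene-style mapping between two species' gene symbols; lookups
#' through the map are case-insensitive and a source symbol may map to
#' several targets.
#'
#' @param path Path to a TSV with columns source_symbol, target_symbol
#'   (header optional; the first two columns are used).
#' @return A data.frame with columns source_symbol, target_symbol.
#' @export
read_homolog_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("source_symbol", first, fixed = TRUE)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE, quote = "")
  out <- df[, 1:2]
  names(out) <- c("source_symbol", "target_symbol")
  out
}

#' An identity homolog map over a symbol set
#' @param symbols Gene symbols.
#' @return A homolog map data.frame mapping each symbol to itself.
#' @export
identity_homolog_map <- function(symbols) {
  data.frame(source_symbol = symbols, target_symbol = symbols,
             stringsAsFactors = FALSE)
}

#' Read a GWAS Catalog association table
#'
#' Honors the catalog's MAPPED_GENE and DISEASE/TRAIT columns (lowercase
#' mapped_gene / trait also accepted).
#'
#' @param path Path to the TSV.
#' @return A data.frame with (at least) columns mapped_gene, trait.
#' @export
read_gwas_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  gene_col <- intersect(c("MAPPED_GENE", "mapped_gene"), names(df))[1]
  trait_col <- intersect(c("DISEASE/TRAIT", "DISEASE.TRAIT", "trait"), names(df))[1]
  if (is.na(gene_col) || is.na(trait_col))
    stop("GWAS table must carry MAPPED_GENE and DISEASE/TRAIT columns")
  out <- df
  out$mapped_gene <- df[[gene_col]]
  out$trait <- df[[trait_col]]
  out
}

#' Read named gene sets from a GMT file
#' @param path Path to a standard GMT file (set name, description, members).
#' @return A named list of character vectors of member symbols.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- readLines(path)
  fields <- strsplit(lines[nzchar(lines)], "\t", fixed = TRUE)
  stats::setNames(lapply(fields, function(f) f[-(1:2)]),
                  vapply(fields, `[[`, "", 1L))
}

#' Read a cohort manifest
#'
#' Binds sample files to groups: TSV with columns sample_id, path, group and
#' optionally tissue, protocol.
#'
#' @param path Path to the manifest TSV (header required).
#' @return A data.frame.
#' @export
read_manifest <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  need <- c("sample_id", "path", "group")
  if (!all(need %in% names(df)))
    stop("manifest must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in manifest")
  df
}

#' Load every sample table listed in a manifest
#' @param manifest Manifest data.frame (see [read_manifest()]).
#' @param base_dir Directory that relative paths in the manifest resolve
#'   against (default: the manifest's own notion of the working directory).
#' @return A named list of eccDNA record data.frames, one per sample.
#' @export
load_cohort <- function(manifest, base_dir = ".") {
  paths <- ifelse(grepl("^/", manifest$path), manifest$path,
                  file.path(base_dir, manifest$path))
  stats::setNames(
    lapply(seq_len(nrow(manifest)),
           function(i) read_eccdna_table(paths[i], manifest$sample_id[i])),
    manifest$sample_id)
}
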