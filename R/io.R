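#' @importFrom Biostrings readDNAStringSet DNAStringSet reverseComplement
#' @importFrom IRanges IRanges reduce findOverlaps pintersect width start end
#' @importFrom S4Vectors queryHits subjectHits
NULL

IUPAC_LETTERS <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V")

#' Read a multi-record FASTA file
#'
#' Sequences are uppercased on input; all internal coordinates downstream
#' are 0-based half-open.
#'
#' @param path Path to a FASTA file.
#' @param topology `"linear"` (default) or `"circular"`, applied to every
#'   contig in the file.
#' @return A data.frame with columns `contig_id`, `sequence`, `length`,
#'   `topology`, one row per record, in file order.
#' @export
parse_fasta <- function(path, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("no records in FASTA file ", path)
  if (any(Biostrings::width(set) == 0L)) {
    bad <- names(set)[Biostrings::width(set) == 0L][1L]
    stop("FASTA record with empty sequence: ", bad)
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) stop("duplicate contig ids in ", path)
  data.frame(
    contig_id = ids,
    sequence  = toupper(as.character(set)),
    length    = Biostrings::width(set),
    topology  = topology,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write genome records to FASTA
#'
#' @param genome data.frame as returned by [parse_fasta()].
#' @param path Output path.
#' @param width Line wrap width in bases.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(genome))) {
    writeLines(paste0(">", genome$contig_id[i]), con)
    s <- genome$sequence[i]
    n <- nchar(s)
    starts <- seq.int(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

gff_attr <- function(attrs, key) {
  pat <- paste0("(?:^|;)\\s*", key, "=([^;]*)")
  m <- regmatches(attrs, regexec(pat, attrs))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
         character(1))
}

#' Parse gene-model features from a GFF3 file
#'
#' GFF3 1-based inclusive coordinates are converted to the package's
#' 0-based half-open convention.  Records with `end < start` or with a
#' missing strand are skipped with a warning.  The gene biotype is read
#' from the `gene_biotype` (or `biotype`) attribute when present; a gene
#' is `protein_coding` iff the attribute says so, any other stated
#' biotype is classed `noncoding`, and an absent attribute is `unknown`.
#'
#' @param path Path to a GFF3 file.
#' @param kinds Character vector of feature kinds to keep
#'   (column 3 values, e.g. `c("gene", "exon", "CDS")`).
#' @return A data.frame of features with columns `contig_id`, `start`,
#'   `end` (0-based half-open), `strand`, `kind`, `gene_id`, `biotype`.
#' @export
parse_gff_features <- function(path, kinds = c("gene", "exon", "CDS")) {
  if (length(kinds) == 0L) stop("kinds must be nonempty")
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  empty <- data.frame(
    contig_id = character(), start = integer(), end = integer(),
    strand = character(), kind = character(), gene_id = character(),
    biotype = character(), stringsAsFactors = FALSE
  )
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    warning(sum(nf < 9L), " GFF3 line(s) with fewer than 9 fields skipped")
    fields <- fields[nf >= 9L]
  }
  if (length(fields) == 0L) return(empty)
  mat <- do.call(rbind, lapply(fields, `[`, 1:9))
  keep <- mat[, 3L] %in% kinds
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) == 0L) return(empty)

  start1 <- suppressWarnings(as.integer(mat[, 4L]))
  end1 <- suppressWarnings(as.integer(mat[, 5L]))
  bad <- is.na(start1) | is.na(end1) | end1 < start1
  if (any(bad)) {
    warning(sum(bad), " GFF3 record(s) with end < start or unparsable ",
            "coordinates skipped")
  }
  nostrand <- !mat[, 7L] %in% c("+", "-")
  if (any(nostrand & !bad)) {
    warning(sum(nostrand & !bad),
            " GFF3 record(s) without a defined strand skipped")
  }
  keep <- !bad & !nostrand
  mat <- mat[keep, , drop = FALSE]
  if (nrow(mat) == 0L) return(empty)

  attrs <- mat[, 9L]
  id <- gff_attr(attrs, "ID")
  parent <- gff_attr(attrs, "Parent")
  gid <- gff_attr(attrs, "gene_id")
  gene_id <- ifelse(!is.na(gid), gid,
                    ifelse(mat[, 3L] == "gene" & !is.na(id), id,
                           ifelse(!is.na(parent), parent,
                                  ifelse(!is.na(id), id, NA_character_))))
  gene_id <- sub("^(gene:|transcript:)", "", gene_id)
  bt <- gff_attr(attrs, "gene_biotype")
  bt2 <- gff_attr(attrs, "biotype")
  bt[is.na(bt)] <- bt2[is.na(bt)]
  biotype <- ifelse(is.na(bt), "unknown",
                    ifelse(bt == "protein_coding", "protein_coding",
                           "noncoding"))
  data.frame(
    contig_id = mat[, 1L],
    start = start1[keep] - 1L,
    end = end1[keep],
    strand = mat[, 7L],
    kind = mat[, 3L],
    gene_id = gene_id,
    biotype = biotype,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write features to GFF3 (0-based half-open back to 1-based inclusive)
#'
#' @param features Feature data.frame as from [parse_gff_features()].
#' @param path Output path.
#' @export
write_gff_features <- function(features, path) {
  ord <- order(features$contig_id, features$start, features$end,
               features$strand)
  f <- features[ord, , drop = FALSE]
  attrs <- ifelse(
    f$kind == "gene",
    paste0("ID=", f$gene_id,
           ifelse(f$biotype == "unknown", "",
                  paste0(";gene_biotype=",
                         ifelse(f$biotype == "protein_coding",
                                "protein_coding", f$biotype)))),
    paste0("Parent=", f$gene_id)
  )
  lines <- paste(f$contig_id, "g4topo", f$kind, f$start + 1L, f$end, ".",
                 f$strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Derive introns from exons
#'
#' For each gene, introns are the gaps between coordinate-sorted
#' consecutive exons; exons are unioned per gene first (overlapping
#' exons trigger a warning and are merged), so alternative transcripts
#' collapse to one exon chain per gene.
#'
#' @param exons Feature data.frame of kind `exon` with `gene_id` set.
#' @return Feature data.frame of kind `intron`.
#' @export
derive_introns <- function(exons) {
  out <- list()
  for (g in unique(exons$gene_id)) {
    ex <- exons[exons$gene_id == g, , drop = FALSE]
    if (length(unique(ex$contig_id)) > 1L || length(unique(ex$strand)) > 1L)
      stop("exons of gene ", g, " span multiple contigs or strands")
    ir <- IRanges::IRanges(start = ex$start + 1L, end = ex$end)
    red <- IRanges::reduce(ir, min.gapwidth = 0L)   # keep abutting apart
    if (length(red) < length(ir))
      warning("overlapping/duplicate exons of gene ", g, " merged")
    if (length(red) < 2L) next
    s <- IRanges::end(red)[-length(red)]        # 0-based intron starts
    e <- IRanges::start(red)[-1L] - 1L          # exclusive intron ends
    keep <- e > s
    if (!any(keep)) next
    out[[g]] <- data.frame(
      contig_id = ex$contig_id[1L], start = s[keep], end = e[keep],
      strand = ex$strand[1L], kind = "intron", gene_id = g,
      biotype = ex$biotype[1L], stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(contig_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      kind = character(), gene_id = character(),
                      biotype = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

#' Read a BED3/BED6 file
#'
#' @param path Path to a BED file.
#' @return data.frame with columns `contig_id`, `start`, `end`, `name`,
#'   `score`, `strand` (BED3 input gets `name = "."`, `score = NA`,
#'   `strand = "."`).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#",
                           colClasses = "character")
  if (ncol(raw) < 3L) stop("BED file needs at least 3 columns: ", path)
  start <- as.integer(raw[[2L]])
  end <- as.integer(raw[[3L]])
  if (any(is.na(start) | is.na(end)))
    stop("non-numeric BED coordinates in ", path)
  if (any(start >= end)) {
    i <- which(start >= end)[1L]
    stop("BED interval with start >= end at line ", i, " of ", path)
  }
  data.frame(
    contig_id = raw[[1L]],
    start = start,
    end = end,
    name = if (ncol(raw) >= 4L) raw[[4L]] else ".",
    score = if (ncol(raw) >= 5L) raw[[5L]] else NA_character_,
    strand = if (ncol(raw) >= 6L) raw[[6L]] else ".",
    stringsAsFactors = FALSE
  )
}

#' Write intervals to BED6
#'
#' Output is deterministic: rows sorted by contig, start, end, strand.
#' Scores given as strings are preserved textually.
#'
#' @param intervals data.frame with at least `contig_id`, `start`, `end`;
#'   optional `name`, `score`, `strand`.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  x <- intervals
  if (is.null(x$name)) x$name <- "."
  if (is.null(x$score)) x$score <- "0"
  if (is.null(x$strand)) x$strand <- "."
  if (any(x$start >= x$end)) stop("interval with start >= end")
  sc <- ifelse(is.na(x$score), "0", as.character(x$score))
  ord <- order(x$contig_id, x$start, x$end, x$strand)
  lines <- paste(x$contig_id[ord], x$start[ord], x$end[ord], x$name[ord],
                 sc[ord], x$strand[ord], sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Reverse-complement a nucleotide string
#'
#' @param seq Uppercase nucleotide string (IUPAC letters allowed).
#' @return The reverse complement as a character string.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# 0-based half-open data.frame -> IRanges (1-based inclusive)
.as_iranges <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

#' Write a report table as TSV with a one-line header
#' @param df data.frame to write.
#' @param path Output path.
#' @export
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Deduplicate assemblies by species, preferring RefSeq
#'
#' When two assembly records share a species key, the one flagged
#' `refseq` wins (RefSeq annotation is the more comprehensive); among
#' ties the first listed is kept.  This is an input-selection policy,
#' applied before any scanning.
#'
#' @param assemblies data.frame with at least `species_key` and a
#'   logical `refseq` column; remaining columns are carried through.
#' @return The deduplicated data.frame, one row per species key.
#' @export
select_assemblies <- function(assemblies) {
  stopifnot(all(c("species_key", "refseq") %in% names(assemblies)))
  ord <- order(assemblies$species_key, !assemblies$refseq)
  a <- assemblies[ord, , drop = FALSE]
  a <- a[!duplicated(a$species_key), , drop = FALSE]
  row.names(a) <- NULL
  a
}
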