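## Genome input: GenBank flat files or FASTA plus a tab-delimited gene table,
## IUPAC ambiguity resolution, and the gene filters applied before codon-usage
## estimation.

#' IUPAC ambiguity substitution table
#'
#' The eleven ambiguous IUPAC nucleotide symbols and the set of concrete
#' nucleotides each may stand for.
#'
#' @return named list mapping each symbol (R, Y, M, K, S, W, B, D, H, V, N)
#'   to a character vector of possible substitutions.
#' @export
ambiguity_table <- function() {
  list(
    R = c("A", "G"),
    Y = c("C", "T"),
    M = c("A", "C"),
    K = c("G", "T"),
    S = c("C", "G"),
    W = c("A", "T"),
    B = c("C", "G", "T"),
    D = c("A", "G", "T"),
    H = c("A", "C", "T"),
    V = c("A", "C", "G"),
    N = c("A", "G", "C", "T")
  )
}

#' Replace ambiguous IUPAC symbols by concrete nucleotides
#'
#' Every non-ACGT IUPAC symbol is replaced by a nucleotide drawn uniformly
#' from its substitution set (see [ambiguity_table()]), using a seeded
#' generator so the resolution is reproducible.  Unambiguous positions are
#' untouched.
#'
#' @param sequence character scalar over the 15 IUPAC nucleotide symbols.
#' @param seed integer seed for the substitution draws (default 0).
#' @return character scalar of the same length over \{A,C,G,T\}.
#' @export
substitute_ambiguous <- function(sequence, seed = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  tab <- ambiguity_table()
  ok <- chars %in% c("A", "C", "G", "T")
  if (all(ok)) return(sequence)
  amb <- which(!ok)
  bad <- !(chars[amb] %in% names(tab))
  if (any(bad)) {
    stop("character outside the IUPAC nucleotide alphabet: '",
         chars[amb[bad][1L]], "' at position ", amb[bad][1L])
  }
  with_seed(seed, {
    # draw symbols in sequence order so the result depends only on (sequence, seed)
    chars[amb] <- vapply(chars[amb], function(s) {
      set <- tab[[s]]
      set[sample.int(length(set), 1L)]
    }, character(1L))
  })
  paste0(chars, collapse = "")
}

new_genome_record <- function(accession, sequence, raw_sequence, topology, genes) {
  stopifnot(nchar(sequence) >= 3L)
  structure(
    list(
      accession = accession,
      sequence = sequence,
      raw_sequence = raw_sequence,
      topology = topology,
      genes = genes
    ),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$accession, ": ", nchar(x$sequence), " bp (",
      x$topology, "), ", nrow(x$genes), " annotated genes\n", sep = "")
  invisible(x)
}

empty_gene_table <- function() {
  data.frame(
    gene_id = character(0), start = integer(0), end = integer(0),
    strand = character(0), stringsAsFactors = FALSE
  )
}

## --- GenBank flat-file parsing -------------------------------------------
## No installed package parses *local* GenBank flat files, so a minimal
## parser for LOCUS / FEATURES (CDS only) / ORIGIN is implemented here.
## Supported locations: "start..end" and "complement(start..end)".
## join()/order() locations, wrap-around spans and pseudo genes are skipped
## with a warning.

parse_genbank <- function(lines) {
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0L) stop("not a GenBank flat file: no LOCUS line")
  if (length(locus_i) > 1L) {
    message("multi-record GenBank file: only the first record is analyzed")
    lines <- lines[seq_len(locus_i[2L] - 1L)]
  }
  locus <- strsplit(trimws(lines[locus_i[1L]]), "[[:space:]]+")[[1L]]
  accession <- if (length(locus) >= 2L) locus[2L] else "unknown"
  topology <- if (any(grepl("circular", lines[locus_i[1L]]))) "circular" else "linear"

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) != 1L) stop("GenBank record has no ORIGIN section")
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[end_i > origin_i][1L] else length(lines) + 1L
  seq_lines <- lines[seq.int(origin_i + 1L, end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste0(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("empty sequence in GenBank record")

  feat_i <- grep("^FEATURES", lines)
  genes <- empty_gene_table()
  if (length(feat_i) == 1L) {
    block <- lines[seq.int(feat_i + 1L, origin_i - 1L)]
    key_i <- grep("^ {5}[A-Za-z]", block)
    cds_i <- grep("^ {5}CDS ", block)
    n_skip <- 0L
    rows <- vector("list", length(cds_i))
    for (i in cds_i) {
      nxt <- key_i[key_i > i]
      feat_end <- if (length(nxt)) nxt[1L] - 1L else length(block)
      feat <- block[i:feat_end]
      loc <- sub("^ {5}CDS +", "", feat[1L])
      pseudo <- any(grepl("^ +/pseudo\\b", feat))
      lt <- grep("^ +/locus_tag=", feat, value = TRUE)
      gid <- if (length(lt)) gsub(".*=\"?([^\"]*)\"?.*", "\\1", lt[1L]) else loc
      strand <- "+"
      if (grepl("^complement\\(", loc)) {
        strand <- "-"
        loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
      }
      if (pseudo || !grepl("^<?[0-9]+\\.\\.>?[0-9]+$", loc)) {
        n_skip <- n_skip + 1L
        next
      }
      pos <- as.integer(strsplit(gsub("[<>]", "", loc), "..", fixed = TRUE)[[1L]])
      if (pos[1L] > pos[2L] || pos[2L] > nchar(sequence)) {
        n_skip <- n_skip + 1L  # wrap-around or out-of-range span
        next
      }
      rows[[match(i, cds_i)]] <- data.frame(
        gene_id = gid, start = pos[1L], end = pos[2L], strand = strand,
        stringsAsFactors = FALSE
      )
    }
    rows <- rows[!vapply(rows, is.null, logical(1L))]
    if (length(rows)) genes <- do.call(rbind, rows)
    if (n_skip > 0L) {
      warning(n_skip, " CDS feature(s) skipped (pseudo, join/complex or wrap-around location)")
    }
  }
  list(accession = accession, topology = topology, sequence = sequence, genes = genes)
}

#' Read a genome with its gene annotations
#'
#' Reads either a GenBank flat file (sequence plus CDS features) or a FASTA
#' file accompanied by a tab-delimited gene table with columns
#' `gene_id`, `start`, `end`, `strand` (1-based inclusive coordinates,
#' strand `+`/`-`).  Ambiguous IUPAC symbols in the sequence are resolved by
#' [substitute_ambiguous()]; the raw sequence is retained for the
#' terminal-codon ambiguity check in [filter_genes()].  The annotation list
#' is attached unfiltered.
#'
#' @param path path to the GenBank or FASTA file.
#' @param format `"genbank"` or `"fasta"`.
#' @param gene_table for `format = "fasta"`, path to the TSV gene table
#'   (optional; omit for an unannotated sequence).
#' @param seed seed forwarded to [substitute_ambiguous()].
#' @return a `genome_record` with fields `accession`, `sequence` (resolved),
#'   `raw_sequence`, `topology` and `genes`.
#' @export
read_genome <- function(path, format = c("genbank", "fasta"),
                        gene_table = NULL, seed = 0L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "genbank") {
    gb <- parse_genbank(readLines(path, warn = FALSE))
    raw <- gb$sequence
    acc <- gb$accession
    topo <- gb$topology
    genes <- gb$genes
  } else {
    ss <- Biostrings::readDNAStringSet(path)
    if (length(ss) == 0L || nchar(as.character(ss[[1L]])) == 0L) {
      stop("empty FASTA sequence")
    }
    if (length(ss) > 1L) message("multi-sequence FASTA: only the first sequence is analyzed")
    raw <- toupper(as.character(ss[[1L]]))
    acc <- strsplit(names(ss)[1L], "[[:space:]]+")[[1L]][1L]
    topo <- "linear"
    genes <- if (is.null(gene_table)) empty_gene_table() else {
      gt <- utils::read.delim(gene_table, stringsAsFactors = FALSE)
      need <- c("gene_id", "start", "end", "strand")
      if (!all(need %in% names(gt))) {
        stop("gene table must have columns ", paste(need, collapse = ", "))
      }
      gt[, need]
    }
  }
  if (nrow(genes) > 0L) {
    ok <- genes$start >= 1L & genes$start <= genes$end & genes$end <= nchar(raw) &
      genes$strand %in% c("+", "-")
    if (!all(ok)) {
      warning(sum(!ok), " gene(s) with invalid coordinates or strand dropped")
      genes <- genes[ok, , drop = FALSE]
    }
  }
  resolved <- substitute_ambiguous(raw, seed = seed)
  new_genome_record(acc, resolved, raw, topo, genes)
}

#' Filter annotated genes before codon-usage estimation
#'
#' Keeps genes whose span is a multiple of three and whose first and last
#' codon regions were free of ambiguity symbols in the raw (pre-substitution)
#' sequence.  Removed genes are reported with a message.
#'
#' @param record a `genome_record` from [read_genome()].
#' @return the gene annotation data frame restricted to the genes kept,
#'   original order preserved.
#' @export
filter_genes <- function(record) {
  stopifnot(inherits(record, "genome_record"))
  genes <- record$genes
  if (nrow(genes) == 0L) return(genes)
  span <- genes$end - genes$start + 1L
  mod3 <- span %% 3L == 0L
  term_clean <- vapply(seq_len(nrow(genes)), function(i) {
    first <- substr(record$raw_sequence, genes$start[i], genes$start[i] + 2L)
    last <- substr(record$raw_sequence, genes$end[i] - 2L, genes$end[i])
    grepl("^[ACGT]+$", first) && grepl("^[ACGT]+$", last)
  }, logical(1L))
  keep <- mod3 & term_clean
  if (any(!keep)) {
    for (i in which(!keep)) {
      message("filter_genes: dropping ", genes$gene_id[i], " (",
              if (!mod3[i]) "span not a multiple of 3" else "ambiguous terminal codon", ")")
    }
  }
  genes[keep, , drop = FALSE]
}

#' Write the resolved genome sequence as FASTA
#'
#' @param record a `genome_record`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(record, path) {
  stopifnot(inherits(record, "genome_record"))
  x <- Biostrings::DNAStringSet(record$sequence)
  names(x) <- record$accession
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
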