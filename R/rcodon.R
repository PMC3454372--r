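## Rcodon: artificial random genomes of IID codons drawn from a codon usage,
## plus a writer for minimal GenBank fixtures used in tests and examples.

#' Simulate an Rcodon random genome
#'
#' Draws `floor(length_bp/3)` codons independently from the usage and
#' concatenates them.  By definition, all frame +1 ORFs of an Rcodon
#' sequence are its "annotated" ORFs; the returned string carries an
#' `annotated_frame` attribute recording that convention.
#'
#' @param usage a `codon_usage`.
#' @param length_bp target length in bp (truncated down to a multiple of 3).
#' @param seed integer seed; the same (usage, length, seed) triple always
#'   yields the same sequence.
#' @return character scalar over \{A,C,G,T\} with attribute
#'   `annotated_frame = "+1"`.
#' @export
rcodon_simulate <- function(usage, length_bp, seed = 0L) {
  usage <- as_codon_usage(usage)
  stopifnot(length_bp >= 3)
  ncod <- length_bp %/% 3
  idx <- with_seed(seed, sample.int(64L, ncod, replace = TRUE, prob = unclass(usage)))
  structure(paste0(CODONS[idx], collapse = ""), annotated_frame = "+1")
}

#' Random strictly positive codon usage
#'
#' Convenience generator for simulation studies: a symmetric
#' Dirichlet(`concentration`) draw over the 64 codons.  Every codon gets
#' positive mass, so all frame-shift chains are ergodic.
#'
#' @param seed integer seed.
#' @param concentration Dirichlet concentration parameter (1 = flat).
#' @return a `codon_usage`.
#' @export
random_usage <- function(seed = 0L, concentration = 1) {
  g <- with_seed(seed, stats::rgamma(64L, shape = concentration))
  g <- pmax(g, 1e-12)
  as_codon_usage(g, source = paste0("random_usage(seed=", seed, ")"))
}

#' Uniform codon usage (all 64 codons equiprobable)
#'
#' @return a `codon_usage` with probability 1/64 per codon.
#' @export
uniform_usage <- function() {
  as_codon_usage(rep(1 / 64, 64L), source = "uniform")
}

#' Synthetic bacterial-like codon usage
#'
#' Emulates the codon usage of an annotated bacterial gene set at a given
#' genomic GC content.  Three features of real usages are reproduced:
#' position-dependent nucleotide composition (the third codon position
#' carries most of the GC signal, the second position is AT-shifted),
#' codon-to-codon preference scatter (multiplicative log-normal noise on a
#' product-form baseline), and the rarity of stop codons, whose total mass
#' equals `1/(mean_gene_len + 1)` because one stop is counted per gene when
#' usage is estimated from concatenated annotated ORFs.
#'
#' @param gc genomic GC content in (0, 1).
#' @param seed integer seed for the codon-preference noise.
#' @param mean_gene_len mean annotated gene length in codons (default 300).
#' @param sdlog standard deviation of the log-normal codon preference noise.
#' @return a `codon_usage`.
#' @export
bacterial_usage <- function(gc = 0.5, seed = 0L, mean_gene_len = 300,
                            sdlog = 0.35) {
  stopifnot(gc > 0, gc < 1, mean_gene_len >= 2)
  # per-position GC: codon position 3 amplifies the genomic signal,
  # position 2 is damped and AT-shifted, position 1 slightly GC-shifted
  squash <- function(x) pmin(pmax(x, 0.05), 0.95)
  gc1 <- squash(gc + 0.05)
  gc2 <- squash(0.5 * (gc - 0.5) + 0.42)
  gc3 <- squash(1.8 * (gc - 0.5) + 0.5)
  pos <- function(gcp, purine = 0.5) {
    # split GC between G and C and AT between A and T; purine > 0.5 favors
    # A and G (position 1 of real genes is purine-rich)
    c(A = (1 - gcp) * purine, C = gcp * (1 - purine),
      G = gcp * purine, T = (1 - gcp) * (1 - purine))
  }
  p1 <- pos(gc1, purine = 0.60)
  p2 <- pos(gc2, purine = 0.50)
  p3 <- pos(gc3, purine = 0.50)
  base <- vapply(CODONS, function(cd) {
    s <- strsplit(cd, "")[[1L]]
    p1[s[1L]] * p2[s[2L]] * p3[s[3L]]
  }, numeric(1L))
  noise <- with_seed(seed, exp(stats::rnorm(64L, sd = sdlog)))
  p <- base * noise
  # fix the total stop mass to one terminal stop per gene
  stop_i <- codon_index(DEFAULT_STOPS)
  stop_mass <- 1 / (mean_gene_len + 1)
  p[stop_i] <- p[stop_i] / sum(p[stop_i]) * stop_mass
  p[-stop_i] <- p[-stop_i] / sum(p[-stop_i]) * (1 - stop_mass)
  as_codon_usage(p, source = sprintf("bacterial_usage(gc=%g,seed=%d)", gc, seed))
}

#' Write a minimal GenBank fixture
#'
#' Assembles a genome from gene codon strings and spacer sequences and
#' writes a minimal valid GenBank flat file with one CDS feature per gene,
#' suitable for round-tripping through [read_genome()].
#'
#' @param genes character vector of gene sequences (start codon + body +
#'   stop codon, length divisible by 3), given on the coding strand.
#' @param strands strand per gene, `+` or `-` (default all `+`); a `-` gene
#'   is inserted as its reverse complement with a `complement()` location.
#' @param spacers character vector of nucleotide strings placed around the
#'   genes: either `length(genes) - 1` (between genes only) or
#'   `length(genes) + 1` (leading, between, trailing).
#' @param path output file path.
#' @param accession record name written to the LOCUS line.
#' @return invisible list with the assembled `sequence` and the gene
#'   coordinate table.
#' @export
make_genbank_fixture <- function(genes, strands = NULL, spacers = character(0),
                                 path, accession = "TOY0001") {
  stopifnot(length(genes) >= 0L)
  if (is.null(strands)) strands <- rep("+", length(genes))
  stopifnot(length(strands) == length(genes), all(strands %in% c("+", "-")))
  genes <- toupper(gsub("[[:space:]]", "", genes))
  if (any(nchar(genes) %% 3L != 0L)) stop("gene length not divisible by 3")
  ngap <- length(spacers)
  if (!(ngap %in% c(0L, max(length(genes) - 1L, 0L), length(genes) + 1L))) {
    stop("spacers must number length(genes)-1 or length(genes)+1")
  }
  lead <- if (ngap == length(genes) + 1L) spacers[1L] else ""
  trail <- if (ngap == length(genes) + 1L) spacers[length(spacers)] else ""
  between <- if (ngap == length(genes) + 1L) {
    spacers[-c(1L, length(spacers))]
  } else spacers

  seq_parts <- character(0)
  rows <- list()
  pos <- nchar(lead)
  seq_parts <- c(seq_parts, lead)
  for (i in seq_along(genes)) {
    gseq <- if (strands[i] == "-") revcomp(genes[i]) else genes[i]
    rows[[i]] <- data.frame(
      gene_id = sprintf("toy_%03d", i),
      start = pos + 1L, end = pos + nchar(gseq), strand = strands[i],
      stringsAsFactors = FALSE
    )
    seq_parts <- c(seq_parts, gseq)
    pos <- pos + nchar(gseq)
    if (i < length(genes) && length(between) >= i) {
      seq_parts <- c(seq_parts, between[i])
      pos <- pos + nchar(between[i])
    }
  }
  seq_parts <- c(seq_parts, trail)
  sequence <- paste0(seq_parts, collapse = "")
  if (nchar(sequence) < 3L) stop("fixture sequence shorter than 3 bp")
  genes_df <- if (length(rows)) do.call(rbind, rows) else empty_gene_table()

  lines <- c(
    sprintf("LOCUS       %s %d bp    DNA     linear   UNA 01-JAN-2000",
            accession, nchar(sequence)),
    sprintf("DEFINITION  synthetic toy genome %s.", accession),
    sprintf("ACCESSION   %s", accession),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", nchar(sequence))
  )
  for (i in seq_len(nrow(genes_df))) {
    loc <- sprintf("%d..%d", genes_df$start[i], genes_df$end[i])
    if (genes_df$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    lines <- c(lines,
               sprintf("     CDS             %s", loc),
               sprintf("                     /locus_tag=\"%s\"", genes_df$gene_id[i]))
  }
  lines <- c(lines, "ORIGIN")
  for (o in seq.int(1L, nchar(sequence), by = 60L)) {
    chunk <- substr(sequence, o, min(o + 59L, nchar(sequence)))
    blocks <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", o, paste(blocks, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(list(sequence = sequence, genes = genes_df))
}
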