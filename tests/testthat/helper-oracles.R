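# Independent oracles used across the suite.

# Brute-force six-frame ORF enumerator: for every stop codon, collect all
# start codons upstream in the same frame with no stop in between, and keep
# the most upstream one (longest ORF per stop).  Deliberately implemented by
# substring loops, independent of the scanner's findInterval path.
brute_force_orfs <- function(sequence, start_set = c("ATG", "GTG", "TTG", "CTG"),
                             stop_set = c("TAA", "TAG", "TGA")) {
  n <- nchar(sequence)
  scan_one <- function(s, frame_labels, map_coords) {
    rows <- list()
    for (off in 0:2) {
      ncod <- (nchar(s) - off) %/% 3
      if (ncod < 1) next
      pos1 <- off + 3 * (seq_len(ncod) - 1) + 1
      trips <- substring(s, pos1, pos1 + 2)
      stop_i <- which(trips %in% stop_set)
      start_i <- which(trips %in% start_set)
      for (sp in stop_i) {
        cand <- start_i[start_i < sp]
        ok <- cand[vapply(cand, function(i) !any(stop_i > i & stop_i < sp),
                          logical(1))]
        if (length(ok) == 0) next
        st <- min(ok)
        coords <- map_coords(pos1[st], pos1[sp] + 2)
        rows[[length(rows) + 1]] <- data.frame(
          frame = frame_labels[off + 1], start_bp = coords[1], end_bp = coords[2],
          stringsAsFactors = FALSE
        )
      }
    }
    rows
  }
  fwd <- scan_one(sequence, c("+1", "+2", "+3"), function(a, b) c(a, b))
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", sequence), "")[[1]]), collapse = "")
  rev_ <- scan_one(rc, c("-1", "-2", "-3"),
                   function(a, b) c(n - b + 1, n - a + 1))
  out <- do.call(rbind, c(fwd, rev_))
  if (is.null(out)) {
    out <- data.frame(frame = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), stringsAsFactors = FALSE)
  }
  out[order(out$frame, out$start_bp), , drop = FALSE]
}

# random A/C/G/T string
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

# empirical codon distribution of a frame-shifted reading of a sequence
empirical_frame_dist <- function(sequence, frame) {
  codes <- orfstat:::seq_to_codes(sequence)
  if (substr(frame, 1, 1) == "-") codes <- orfstat:::revcomp_codes(codes)
  off <- as.integer(substr(frame, 2, 2)) - 1L
  idx <- orfstat:::frame_codon_index(codes, off)
  tabulate(idx, nbins = 64) / length(idx)
}

# fabricate a frame_probabilities object from explicit rho/tau vectors
make_fp <- function(rho, tau) {
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  rho <- rep_len(rho, 6)
  tau <- rep_len(tau, 6)
  fp <- data.frame(frame = frames, rho = rho, tau = tau,
                   stringsAsFactors = FALSE)
  rownames(fp) <- frames
  structure(fp, class = c("frame_probabilities", "data.frame"),
            code = genetic_code_config(), source = "synthetic")
}

# frame probabilities of a random strictly positive usage
random_fp_model <- function(seed) frame_probabilities(random_usage(seed))

# genome record built directly from an Rcodon simulation, declaring its
# frame +1 ORFs as the annotated genes (the Rcodon convention)
rcodon_record <- function(usage, length_bp, seed, accession = "RCODON") {
  s <- as.character(rcodon_simulate(usage, length_bp, seed = seed))
  orfs <- find_orfs(s)
  plus1 <- as.data.frame(orfs)[orfs$frame_absolute == "+1", , drop = FALSE]
  genes <- data.frame(
    gene_id = sprintf("rc_%05d", seq_len(nrow(plus1))),
    start = plus1$start_bp, end = plus1$end_bp, strand = "+",
    stringsAsFactors = FALSE
  )
  fa <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(paste0(">", accession), s), fa)
  utils::write.table(genes, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  read_genome(fa, format = "fasta", gene_table = tsv)
}
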