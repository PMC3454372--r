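# Six-frame scanner, aORF extraction, relative-frame assignment.

test_that("scanner implements the longest-ORF-per-stop definition", {
  o <- find_orfs("ATGAAATAA")
  expect_equal(nrow(o), 1L)
  expect_equal(o$frame_absolute, "+1")
  expect_equal(o$start_bp, 1L)
  expect_equal(o$end_bp, 9L)
  expect_equal(o$length_bp, 9L)
  expect_equal(o$length_codons, 2L)

  # internal ATG does not spawn a second ORF for the same stop
  o2 <- find_orfs("ATGATGAAATAA")
  p1 <- o2[o2$frame_absolute == "+1", ]
  expect_equal(nrow(p1), 1L)
  expect_equal(p1$length_codons, 3L)

  # stop without preceding start emits nothing
  o3 <- find_orfs("AAATAAAAA")
  expect_equal(sum(o3$frame_absolute == "+1"), 0L)

  # reverse-complement ORF: "TTACAT" reads ATGTAA on the minus strand
  o4 <- find_orfs("TTACAT")
  expect_equal(nrow(o4), 1L)
  expect_equal(o4$frame_absolute, "-1")
  expect_equal(o4$strand, "-")
  expect_equal(o4$length_codons, 1L)
  expect_equal(c(o4$start_bp, o4$end_bp), c(1L, 6L))

  # runs without a terminating stop are not emitted
  expect_equal(sum(find_orfs("ATGAAAAAA")$frame_absolute == "+1"), 0L)
  expect_error(find_orfs(""), "empty")
})

test_that("scanning the reverse complement mirrors the ORF set", {
  set.seed(11)
  for (rep in 1:20) {
    s <- random_dna(300, gc = runif(1, 0.3, 0.7))
    a <- as.data.frame(find_orfs(s))
    b <- as.data.frame(find_orfs(revcomp(s)))
    n <- nchar(s)
    # reflect b back onto a's coordinates and flip strands
    b2 <- data.frame(start_bp = n - b$end_bp + 1, end_bp = n - b$start_bp + 1,
                     strand = ifelse(b$strand == "+", "-", "+"))
    key <- function(d) sort(paste(d$strand, d$start_bp, d$end_bp))
    expect_identical(key(a), key(b2))
  }
})

test_that("ORF count never exceeds the number of in-frame stop codons", {
  set.seed(12)
  for (rep in 1:10) {
    s <- random_dna(600)
    o <- find_orfs(s)
    codes <- orfstat:::seq_to_codes(s)
    stop_idx <- orfstat:::codon_index(c("TAA", "TAG", "TGA"))
    stops <- 0L
    for (cc in list(codes, orfstat:::revcomp_codes(codes))) {
      for (off in 0:2) {
        stops <- stops + sum(orfstat:::frame_codon_index(cc, off) %in% stop_idx)
      }
    }
    expect_lte(nrow(o), stops)
  }
})

test_that("aORF extraction spans exactly the annotated range", {
  fa <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c(">t", "AAAATGAAATAATT"), fa)
  write.table(data.frame(gene_id = "g", start = 4, end = 12, strand = "+"),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- read_genome(fa, format = "fasta", gene_table = tsv)
  a <- extract_aorfs(rec, filter_genes(rec))
  expect_equal(a$length_bp, 9L)
  expect_equal(a$length_codons, 2L)
  expect_true(a$is_annotated)

  # minus-strand gene: annotated start at the genomic end coordinate
  writeLines(c(">t", "TTACATCAT"), fa)
  write.table(data.frame(gene_id = "g", start = 1, end = 9, strand = "-"),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rec2 <- read_genome(fa, format = "fasta", gene_table = tsv)
  a2 <- extract_aorfs(rec2, filter_genes(rec2))
  expect_equal(a2$length_codons, 2L)
  expect_equal(a2$strand, "-")
  expect_equal(a2$end_bp, 9L)

  # empty gene list gives an empty set, not an error
  rec3 <- rec2
  rec3$genes <- rec2$genes[0, ]
  a3 <- extract_aorfs(rec3, filter_genes(rec3))
  expect_equal(nrow(a3), 0L)

  # a gene not ending in a stop codon is kept but reported
  writeLines(c(">t", "ATGAAACCC"), fa)
  write.table(data.frame(gene_id = "g", start = 1, end = 9, strand = "+"),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rec4 <- read_genome(fa, format = "fasta", gene_table = tsv)
  expect_message(a4 <- extract_aorfs(rec4, filter_genes(rec4)), "stop")
  expect_equal(nrow(a4), 1L)
})

test_that("relative frame convention matches the frame-shift construction", {
  rf <- orfstat:::relative_frame
  # aORF on +, phase 0
  expect_equal(rf("+", 0L, "+", 0L), "+1")
  expect_equal(rf("+", 1L, "+", 0L), "+2")
  expect_equal(rf("+", 2L, "+", 0L), "+3")
  expect_equal(rf("-", 0L, "+", 0L), "-1")   # antiparallel in-register
  expect_equal(rf("-", 2L, "+", 0L), "-2")   # grid of the +2 chain on the -1 read
  expect_equal(rf("-", 1L, "+", 0L), "-3")
  # aORF on -, phase 0: shifts are measured along the aORF reading direction
  expect_equal(rf("-", 0L, "-", 0L), "+1")
  expect_equal(rf("-", 2L, "-", 0L), "+2")
  expect_equal(rf("+", 0L, "-", 0L), "-1")
  expect_equal(rf("+", 1L, "-", 0L), "-2")
})

test_that("relative-frame assignment agrees with the global Rcodon grid", {
  u <- random_usage(21)
  rec <- rcodon_record(u, 60000, seed = 4)
  genes <- filter_genes(rec)
  aorfs <- extract_aorfs(rec, genes)
  orfs <- assign_naorf_frames(find_orfs(rec$sequence), aorfs)
  # every aORF stop is recovered as an annotated ORF
  expect_equal(sum(orfs$is_annotated), nrow(aorfs))
  # assigned relative frames equal the global frame +1 grid convention
  assigned <- !is.na(orfs$frame_relative) & !orfs$is_annotated
  expect_gt(sum(assigned), 100)
  expect_identical(
    orfs$frame_relative[assigned],
    orfstat:::rcodon_relative_frame(orfs$strand[assigned], orfs$start_bp[assigned])
  )
  # naORFs in gene-free gaps stay unassigned
  gap <- as.data.frame(orfs)[is.na(orfs$frame_relative), ]
  if (nrow(gap) > 0) {
    ov <- vapply(seq_len(nrow(gap)), function(i) {
      any(genes$start <= gap$end_bp[i] & genes$end >= gap$start_bp[i])
    }, logical(1))
    expect_false(any(ov))
  }
})

test_that("orf_statistics uses the lower nearest-rank quantile", {
  df <- data.frame(
    frame_absolute = "+1", strand = "+",
    start_bp = c(1, 101, 201, 301), end_bp = c(1, 101, 201, 301) + c(2, 3, 4, 5) * 3 - 1,
    length_bp = c(2, 3, 4, 5) * 3, length_codons = c(1, 2, 3, 4),
    is_annotated = FALSE, frame_relative = NA_character_,
    stringsAsFactors = FALSE
  )
  o <- orfstat:::new_orf_set(df)
  st <- orf_statistics(o)
  expect_equal(unname(st$quantiles["75%"]), 3)
  df$length_codons <- c(5, 5, 5, 5)
  st2 <- orf_statistics(orfstat:::new_orf_set(df))
  expect_equal(st2$mean_codons, 5)
  expect_equal(st2$max_codons, 5)
  expect_error(orf_statistics(orfstat:::new_orf_set(df[0, ])), "empty")
})

test_that("TSV and BED exports carry correct coordinates", {
  o <- find_orfs("ATGAAATAA", source = "toy")
  tsv <- tempfile(fileext = ".tsv")
  bed <- tempfile(fileext = ".bed")
  write_orfs_tsv(o, tsv)
  back <- read.delim(tsv)
  expect_equal(back$start_bp, 1L)
  expect_equal(back$length_codons, 2L)
  write_orfs_bed(o, bed)
  b <- read.delim(bed, header = FALSE)
  expect_equal(b$V2, 0L)   # 0-based start
  expect_equal(b$V3, 9L)   # half-open end
  expect_equal(b$V6, "+")
})
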