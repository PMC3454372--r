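## Six-frame ORF scanner and relative-reading-frame assignment.
##
## An ORF is the longest run of in-frame triplets from a start codon to the
## next in-frame stop codon: one ORF per stop, beginning at the first start
## codon after the previous in-frame stop.  Runs with a start but no
## terminating stop before the sequence end are not emitted.  Coordinates are
## 1-based inclusive on the forward strand and span start and stop codon;
## length_codons excludes the stop codon (length_bp/3 - 1).

new_orf_set <- function(df, source = NA_character_,
                        start_set = DEFAULT_STARTS, stop_set = DEFAULT_STOPS) {
  rownames(df) <- NULL
  structure(df, class = c("orf_set", "data.frame"),
            source = source, start_set = start_set, stop_set = stop_set)
}

orf_columns <- function() {
  data.frame(
    frame_absolute = character(0), strand = character(0),
    start_bp = integer(0), end_bp = integer(0),
    length_bp = integer(0), length_codons = integer(0),
    is_annotated = logical(0), frame_relative = character(0),
    stringsAsFactors = FALSE
  )
}

# scan one frame given codon indices; returns codon-unit start/stop positions
scan_frame_codons <- function(cod, start_mask, stop_mask) {
  stops <- which(stop_mask[cod])
  if (length(stops) == 0L) return(list(s0 = integer(0), s1 = integer(0)))
  starts <- which(start_mask[cod])
  if (length(starts) == 0L) return(list(s0 = integer(0), s1 = integer(0)))
  prev <- c(0L, stops[-length(stops)])
  k <- findInterval(prev, starts) + 1L           # first start strictly after prev stop
  ok <- k <= length(starts)
  ok[ok] <- starts[k[ok]] < stops[ok]            # need >= 1 codon before the stop
  list(s0 = starts[k[ok]], s1 = stops[ok])
}

#' Find all ORFs in six reading frames
#'
#' Scans the three frames of the given strand and the three frames of its
#' reverse complement.  Frames are labeled `+1`, `+2`, `+3` for forward
#' offsets 0, 1, 2 (relative to position 1) and `-1`, `-2`, `-3` for the
#' corresponding offsets on the reverse complement.
#'
#' @param sequence character scalar over \{A,C,G,T\}.
#' @param start_set start codons (default ATG, GTG, TTG, CTG).
#' @param stop_set stop codons (default TAA, TAG, TGA).
#' @param source optional identifier recorded on the result.
#' @return an `orf_set` data frame with columns `frame_absolute`, `strand`,
#'   `start_bp`, `end_bp`, `length_bp`, `length_codons`, `is_annotated`,
#'   `frame_relative`, sorted by start coordinate.
#' @export
find_orfs <- function(sequence, start_set = DEFAULT_STARTS,
                      stop_set = DEFAULT_STOPS, source = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("empty sequence")
  codes <- seq_to_codes(sequence)
  n <- length(codes)
  start_mask <- stop_mask <- logical(64)
  start_mask[codon_index(start_set)] <- TRUE
  stop_mask[codon_index(stop_set)] <- TRUE
  rc <- revcomp_codes(codes)

  out <- vector("list", 6L)
  for (f in 1:3) {
    off <- f - 1L
    hit <- scan_frame_codons(frame_codon_index(codes, off), start_mask, stop_mask)
    start_bp <- off + 3L * (hit$s0 - 1L) + 1L
    end_bp <- off + 3L * hit$s1
    out[[f]] <- data.frame(
      frame_absolute = rep(paste0("+", f), length(start_bp)),
      strand = rep("+", length(start_bp)),
      start_bp = start_bp, end_bp = end_bp,
      stringsAsFactors = FALSE
    )
  }
  for (f in 1:3) {
    off <- f - 1L
    hit <- scan_frame_codons(frame_codon_index(rc, off), start_mask, stop_mask)
    rc_start <- off + 3L * (hit$s0 - 1L) + 1L
    rc_end <- off + 3L * hit$s1
    out[[3L + f]] <- data.frame(
      frame_absolute = rep(paste0("-", f), length(rc_start)),
      strand = rep("-", length(rc_start)),
      start_bp = n - rc_end + 1L, end_bp = n - rc_start + 1L,
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, out)
  df$length_bp <- df$end_bp - df$start_bp + 1L
  df$length_codons <- df$length_bp %/% 3L - 1L
  df$is_annotated <- rep(FALSE, nrow(df))
  df$frame_relative <- rep(NA_character_, nrow(df))
  df <- df[order(df$start_bp, df$end_bp), ]
  new_orf_set(df, source = source, start_set = start_set, stop_set = stop_set)
}

#' @export
print.orf_set <- function(x, ...) {
  cat("<orf_set> ", nrow(x), " ORFs (", sum(x$is_annotated), " annotated)",
      if (!is.na(attr(x, "source"))) paste0(" from ", attr(x, "source")), "\n",
      sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

## 0-based phase of the codon grid on forward coordinates.  For a + strand
## ORF this is (start-1) mod 3; for a - strand ORF the triplet low ends sit
## at the same residue class as (start-1) mod 3 because the span is a
## multiple of 3.
orf_phase <- function(start_bp) (start_bp - 1L) %% 3L

#' Extract annotated ORFs (aORFs) from filtered genes
#'
#' One aORF per gene, spanning exactly the annotated range (the annotated
#' start codon is the beginning even if upstream in-frame starts exist).
#' Genes whose final coding-strand triplet is not in the stop set are kept
#' but reported, since some annotations lack the stop codon or use
#' read-through.
#'
#' @param record a `genome_record`.
#' @param filtered_genes gene table from [filter_genes()].
#' @param stop_set stop codons used for the terminal-codon check.
#' @return an `orf_set` of annotated ORFs.
#' @export
extract_aorfs <- function(record, filtered_genes, stop_set = DEFAULT_STOPS) {
  stopifnot(inherits(record, "genome_record"))
  n <- nchar(record$sequence)
  g <- filtered_genes
  if (nrow(g) == 0L) return(new_orf_set(orf_columns(), source = record$accession,
                                        stop_set = stop_set))
  if (any(g$start < 1L | g$end > n)) stop("gene range outside sequence")
  span <- g$end - g$start + 1L
  stopifnot(all(span %% 3L == 0L))
  last_triplet <- substr(rep(record$sequence, nrow(g)), g$end - 2L, g$end)
  last_triplet <- ifelse(g$strand == "-",
                         revcomp(substr(rep(record$sequence, nrow(g)), g$start, g$start + 2L)),
                         last_triplet)
  no_stop <- !(last_triplet %in% stop_set)
  if (any(no_stop)) {
    message("extract_aorfs: ", sum(no_stop),
            " gene(s) whose final triplet is not a stop codon (kept)")
  }
  frame <- ifelse(g$strand == "+",
                  paste0("+", ((g$start - 1L) %% 3L) + 1L),
                  paste0("-", ((n - g$end) %% 3L) + 1L))
  df <- data.frame(
    frame_absolute = frame, strand = g$strand,
    start_bp = g$start, end_bp = g$end,
    length_bp = span, length_codons = span %/% 3L - 1L,
    is_annotated = TRUE, frame_relative = "+1",
    gene_id = g$gene_id,
    stringsAsFactors = FALSE
  )
  new_orf_set(df, source = record$accession, stop_set = stop_set)
}

## Relative reading frame of an ORF with respect to an overlapping aORF.
## u is the phase shift of the ORF's codon grid measured along the aORF's
## reading direction; on the same strand u = 0,1,2 gives +1,+2,+3.  On the
## opposite strand u = 0 is the antiparallel in-register frame -1, and the
## frame-shift construction used by the codon model places -2 at u = 2 and
## -3 at u = 1.
relative_frame <- function(orf_strand, orf_phase, a_strand, a_phase) {
  d <- (orf_phase - a_phase) %% 3L
  u <- ifelse(a_strand == "+", d, (-d) %% 3L)
  same <- orf_strand == a_strand
  ifelse(same,
         c("+1", "+2", "+3")[u + 1L],
         c("-1", "-3", "-2")[u + 1L])
}

#' Assign relative reading frames to non-annotated ORFs
#'
#' Marks as annotated every ORF of `all_orfs` that shares strand, stop
#' position and frame with an aORF.  Every remaining (non-annotated) ORF
#' overlapping at least one aORF by one or more bp is assigned a relative
#' frame from the offset and strand of the overlapped aORF (the aORF's own
#' frame is `+1`; `-1` is the antiparallel in-register frame).  Ties between
#' overlapping aORFs go to the largest overlap, then the longer aORF, then
#' the lower start coordinate.  naORFs overlapping no aORF keep
#' `frame_relative = NA` (unassigned).
#'
#' @param all_orfs `orf_set` from [find_orfs()].
#' @param aorfs `orf_set` from [extract_aorfs()] on the same genome.
#' @return `all_orfs` with `is_annotated` and `frame_relative` filled in.
#' @export
assign_naorf_frames <- function(all_orfs, aorfs) {
  df <- as.data.frame(all_orfs)
  a <- as.data.frame(aorfs)
  if (nrow(df) == 0L) return(all_orfs)
  if (nrow(a) == 0L) return(all_orfs)

  # annotated = same strand, same stop-end coordinate, same codon grid
  stop_key <- function(strand, start_bp, end_bp) {
    paste(strand, ifelse(strand == "+", end_bp, start_bp),
          orf_phase(start_bp), sep = ":")
  }
  ann <- stop_key(df$strand, df$start_bp, df$end_bp) %in%
    stop_key(a$strand, a$start_bp, a$end_bp)
  df$is_annotated <- ann
  df$frame_relative[ann] <- "+1"

  na_i <- which(!ann)
  if (length(na_i)) {
    # candidate overlaps via sorted aORF starts: any aORF overlapping [s, e]
    # has start in [s - maxlen + 1, e], a window found with findInterval
    ord <- order(a$start_bp)
    as_ <- a$start_bp[ord]; ae <- a$end_bp[ord]
    maxlen <- max(a$end_bp - a$start_bp + 1L)
    for (i in na_i) {
      s <- df$start_bp[i]; e <- df$end_bp[i]
      lo <- findInterval(s - maxlen, as_) + 1L
      hi <- findInterval(e, as_)
      if (hi < lo) next
      cand <- seq.int(lo, hi)
      cand <- cand[ae[cand] >= s]
      if (length(cand) == 0L) next
      j <- ord[cand]
      ov <- pmin(a$end_bp[j], e) - pmax(a$start_bp[j], s) + 1L
      pick <- order(-ov, -(a$end_bp[j] - a$start_bp[j]), a$start_bp[j])[1L]
      j <- j[pick]
      df$frame_relative[i] <- relative_frame(
        df$strand[i], orf_phase(df$start_bp[i]),
        a$strand[j], orf_phase(a$start_bp[j])
      )
    }
  }
  new_orf_set(df, source = attr(all_orfs, "source"),
              start_set = attr(all_orfs, "start_set"),
              stop_set = attr(all_orfs, "stop_set"))
}

#' Summary statistics of an ORF set
#'
#' @param orfs an `orf_set`.
#' @param probs quantile levels (lower nearest-rank rule), default 0.75.
#' @return list with `count`, `mean_codons`, `quantiles` (named, in codons),
#'   `max_codons` and `frame_counts` (by `frame_relative` when present,
#'   otherwise `frame_absolute`).
#' @export
orf_statistics <- function(orfs, probs = 0.75) {
  if (nrow(orfs) == 0L) stop("empty ORF set")
  len <- orfs$length_codons
  key <- ifelse(is.na(orfs$frame_relative), orfs$frame_absolute, orfs$frame_relative)
  q <- stats::quantile(len, probs = probs, type = 1L, names = FALSE)
  list(
    count = nrow(orfs),
    mean_codons = mean(len),
    quantiles = stats::setNames(q, paste0(probs * 100, "%")),
    max_codons = max(len),
    frame_counts = table(factor(key, levels = c("+1", "+2", "+3", "-1", "-2", "-3")))
  )
}

#' Write an ORF set as TSV
#'
#' @param orfs an `orf_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orfs_tsv <- function(orfs, path) {
  cols <- c("frame_absolute", "frame_relative", "start_bp", "end_bp",
            "length_bp", "length_codons", "is_annotated")
  utils::write.table(as.data.frame(orfs)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an ORF set as BED (0-based half-open)
#'
#' @param orfs an `orf_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orfs_bed <- function(orfs, path) {
  src <- attr(orfs, "source")
  name <- ifelse(is.na(orfs$frame_relative), orfs$frame_absolute, orfs$frame_relative)
  bed <- data.frame(
    chrom = if (is.na(src)) "seq" else src,
    chromStart = orfs$start_bp - 1L,
    chromEnd = orfs$end_bp,
    name = paste0("ORF_", name),
    score = orfs$length_codons,
    strand = orfs$strand,
    stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
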