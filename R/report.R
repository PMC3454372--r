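## Pipeline orchestration: genome -> usage -> model -> Rcodon -> comparison,
## and the shadow-gene candidate screen.

# relative frame of an ORF when the annotated codon grid is the whole
# forward frame +1 (phase 0) -- the Rcodon convention
rcodon_relative_frame <- function(strand, start_bp) {
  p <- orf_phase(start_bp)
  ifelse(strand == "+", c("+1", "+2", "+3")[p + 1L], c("-1", "-3", "-2")[p + 1L])
}

orfset_summary <- function(orfs) {
  st <- orf_statistics(orfs)
  # per-frame counts keyed by assigned relative frame; unassigned naORFs
  # (no aORF overlap) are reported separately
  st$frame_counts <- table(factor(orfs$frame_relative, levels = FRAMES))
  n_a <- sum(orfs$is_annotated)
  n_na <- st$count - n_a
  list(
    total_orfs = st$count,
    aorfs = n_a,
    naorfs = n_na,
    ratio_a_na = if (n_na > 0) n_a / n_na else NA_real_,
    mean_codons = st$mean_codons,
    q75_codons = unname(st$quantiles["75%"]),
    max_codons = st$max_codons,
    frame_counts = st$frame_counts,
    unassigned = sum(is.na(orfs$frame_relative))
  )
}

#' Run the full genome -> usage -> model pipeline
#'
#' Filters the annotation, extracts aORFs, estimates the codon usage
#' (optionally from a gene subset), derives the six frame probabilities and
#' builds the geometric mixture model.
#'
#' @param record a `genome_record`.
#' @param code a [genetic_code_config()].
#' @param gene_subset optional character vector of gene IDs used for the
#'   codon usage (the model is otherwise unchanged).
#' @return list with `genes`, `aorfs`, `usage`, `fp` and `model`.
#' @export
genome_model <- function(record, code = genetic_code_config(),
                         gene_subset = NULL) {
  genes <- filter_genes(record)
  if (nrow(genes) == 0L) stop("no genes left after filtering; codon usage undefined")
  aorfs <- extract_aorfs(record, genes, stop_set = code$stop_set)
  usage <- codon_usage(aorfs, record$sequence, gene_ids = gene_subset)
  fp <- frame_probabilities(usage, code)
  model <- build_model(fp, nchar(record$sequence))
  list(genes = genes, aorfs = aorfs, usage = usage, fp = fp, model = model)
}

#' Compare genome, Rcodon realization and mixture model
#'
#' Runs the full pipeline on an annotated genome: gene filtering, aORF
#' extraction, codon usage, frame probabilities, mixture model, one Rcodon
#' realization of the same length and usage, and six-frame ORF scans of both
#' sequences.  Deterministic for a given `seed`.
#'
#' @param record a `genome_record` with at least one gene surviving
#'   [filter_genes()].
#' @param seed seed driving the Rcodon realization.
#' @param gene_subset optional gene-ID vector for the codon usage.
#' @param code a [genetic_code_config()].
#' @return a `comparison_report` list with per-source summaries (`genome`,
#'   `rcodon`, `model`), the fitted `model`, a per-relative-frame count
#'   table and the per-frame survival of the longest observed naORF.
#' @export
compare_genome <- function(record, seed = 0L, gene_subset = NULL,
                           code = genetic_code_config()) {
  pl <- genome_model(record, code = code, gene_subset = gene_subset)
  model <- pl$model

  orfs <- find_orfs(record$sequence, start_set = code$start_set,
                    stop_set = code$stop_set, source = record$accession)
  orfs <- assign_naorf_frames(orfs, pl$aorfs)

  rseq <- rcodon_simulate(pl$usage, nchar(record$sequence), seed = seed)
  rorfs <- find_orfs(rseq, start_set = code$start_set,
                     stop_set = code$stop_set, source = "Rcodon")
  rorfs$frame_relative <- rcodon_relative_frame(rorfs$strand, rorfs$start_bp)
  rorfs$is_annotated <- rorfs$frame_relative == "+1"

  gsum <- orfset_summary(orfs)
  rsum <- orfset_summary(rorfs)
  N1 <- model$frames["+1", "N"]
  msum <- list(
    total_orfs = model$N,
    aorfs = N1,
    naorfs = model$N - N1,
    ratio_a_na = N1 / (model$N - N1),
    mean_codons = average_orf_length(model),
    q75_codons = length_quantile(model, 0.75),
    max_codons = NA_real_,
    frame_counts = stats::setNames(model$frames$N, model$frames$frame),
    unassigned = 0L
  )

  frame_table <- data.frame(
    frame = FRAMES,
    genome = as.integer(gsum$frame_counts[FRAMES]),
    rcodon = as.integer(rsum$frame_counts[FRAMES]),
    model = as.numeric(model$frames[FRAMES, "N"]),
    stringsAsFactors = FALSE
  )

  na_frames <- setdiff(FRAMES, "+1")
  longest <- lapply(na_frames, function(fr) {
    sel <- !orfs$is_annotated & !is.na(orfs$frame_relative) &
      orfs$frame_relative == fr
    if (!any(sel)) return(NULL)
    lmax <- max(orfs$length_codons[sel])
    data.frame(frame = fr, longest_naorf = lmax,
               survival = orf_survival(model, lmax, frame = fr)$survival,
               stringsAsFactors = FALSE)
  })
  longest <- do.call(rbind, longest[!vapply(longest, is.null, logical(1L))])

  structure(
    list(genome = gsum, rcodon = rsum, model = msum,
         frame_table = frame_table, longest_naorf = longest,
         fitted = model, seed = seed, accession = record$accession),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>", x$accession, "\n")
  row <- function(s) c(total = round(s$total_orfs, 1), aORF = round(s$aorfs, 1),
                       naORF = round(s$naorfs, 1),
                       `a/na` = round(s$ratio_a_na, 4),
                       mean = round(s$mean_codons, 2),
                       q75 = round(s$q75_codons, 1),
                       max = round(s$max_codons, 1))
  print(rbind(genome = row(x$genome), rcodon = row(x$rcodon),
              model = row(x$model)))
  cat("\nPer-frame ORF counts (observed vs expected):\n")
  print(x$frame_table, row.names = FALSE)
  if (!is.null(x$longest_naorf)) {
    cat("\nLongest naORF per alternative frame:\n")
    print(x$longest_naorf, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize a comparison report as JSON
#'
#' @param report a `comparison_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
report_to_json <- function(report, path) {
  strip <- function(s) {
    s$frame_counts <- as.list(stats::setNames(as.numeric(s$frame_counts),
                                              names(s$frame_counts)))
    s
  }
  obj <- list(
    accession = report$accession, seed = report$seed,
    genome = strip(report$genome), rcodon = strip(report$rcodon),
    model = strip(report$model),
    frame_table = report$frame_table,
    longest_naorf = report$longest_naorf
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Screen for shadow-gene candidates
#'
#' Lists non-annotated ORFs whose length is statistically surprising under
#' the mixture model: the per-frame survival probability (frame-specific
#' `N_i` and `rho_i`) of an ORF at least that long is at most `pvalue`.
#' naORFs not overlapping any aORF (unassigned relative frame) are scored
#' with the all-frame mixture survival.
#'
#' @param record a `genome_record`.
#' @param pvalue survival-probability threshold.
#' @param code a [genetic_code_config()].
#' @param gene_subset optional gene-ID vector for the codon usage.
#' @return data frame with columns `frame_relative`, `start_bp`, `end_bp`,
#'   `strand`, `length_codons`, `survival`, sorted ascending by survival.
#' @export
shadow_candidates <- function(record, pvalue = 0.01,
                              code = genetic_code_config(),
                              gene_subset = NULL) {
  stopifnot(pvalue >= 0, pvalue <= 1)
  pl <- genome_model(record, code = code, gene_subset = gene_subset)
  orfs <- find_orfs(record$sequence, start_set = code$start_set,
                    stop_set = code$stop_set, source = record$accession)
  orfs <- assign_naorf_frames(orfs, pl$aorfs)
  na <- as.data.frame(orfs)[!orfs$is_annotated, , drop = FALSE]
  if (nrow(na) == 0L) {
    return(data.frame(frame_relative = character(0), start_bp = integer(0),
                      end_bp = integer(0), strand = character(0),
                      length_codons = integer(0), survival = numeric(0)))
  }
  na$survival <- NA_real_
  for (fr in FRAMES) {
    sel <- !is.na(na$frame_relative) & na$frame_relative == fr
    if (any(sel)) {
      na$survival[sel] <- orf_survival(pl$model, na$length_codons[sel],
                                       frame = fr)$survival
    }
  }
  un <- is.na(na$frame_relative)
  if (any(un)) {
    na$survival[un] <- orf_survival(pl$model, na$length_codons[un])$survival
  }
  out <- na[na$survival <= pvalue,
            c("frame_relative", "start_bp", "end_bp", "strand",
              "length_codons", "survival"), drop = FALSE]
  out <- out[order(out$survival, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}
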