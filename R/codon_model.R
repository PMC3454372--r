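## Codon usage and per-reading-frame start/stop codon probabilities.
##
## The annotated frame (+1) is modeled as IID codons drawn from the genome's
## codon usage.  The antiparallel in-register frame (-1) reads the reverse
## complement of each +1 codon, so its codon distribution is the usage
## composed with reverse complementation.  The shifted frames (+2, +3, -2,
## -3) read triplets straddling two consecutive +1 (or -1) codons; over IID
## codons these triplet sequences are Markov chains with memory one on 64
## states, and their codon distributions are the chains' stationary laws.

#' Genetic code configuration (start and stop codon sets)
#'
#' The default stop set is \{TAA, TAG, TGA\}; most mollicutes (e.g.
#' *Mycoplasma*) read TGA as tryptophan, leaving \{TAA, TAG\}.
#'
#' @param stop_set stop codons.
#' @param start_set start codons (default the NTG set ATG, GTG, TTG, CTG).
#' @return a `genetic_code_config` list with `start_set` and `stop_set`.
#' @export
genetic_code_config <- function(stop_set = DEFAULT_STOPS,
                                start_set = DEFAULT_STARTS) {
  stopifnot(length(stop_set) > 0L, length(start_set) > 0L)
  codon_index(stop_set); codon_index(start_set)
  if (length(intersect(stop_set, start_set)) > 0L) {
    stop("start and stop sets must be disjoint")
  }
  structure(list(start_set = start_set, stop_set = stop_set),
            class = "genetic_code_config")
}

#' Mollicute genetic code (TGA is not a stop)
#' @rdname genetic_code_config
#' @export
mollicute_code <- function() genetic_code_config(stop_set = MOLLICUTE_STOPS)

as_codon_usage <- function(p, source = NA_character_) {
  if (!is.null(names(p))) p <- p[CODONS]
  p <- as.numeric(p)
  stopifnot(length(p) == 64L, all(is.finite(p)), all(p >= 0))
  s <- sum(p)
  if (s <= 0) stop("zero total codon probability")
  structure(stats::setNames(p / s, CODONS), class = "codon_usage", source = source)
}

#' @export
print.codon_usage <- function(x, ...) {
  cat("<codon_usage>", if (!is.na(attr(x, "source"))) attr(x, "source") else "",
      "- top codons:\n")
  print(round(sort(unclass(x), decreasing = TRUE)[1:8], 4))
  invisible(x)
}

#' Codon usage from annotated ORFs
#'
#' The usage is the number of occurrences of each codon in the concatenation
#' of all annotated ORFs — read on the coding strand and including each
#' gene's terminal stop codon — divided by the total codon count.
#'
#' @param aorfs an `orf_set` of annotated ORFs ([extract_aorfs()]).
#' @param sequence the genome sequence the coordinates refer to.
#' @param gene_ids optional character vector restricting the usage to a gene
#'   subset (matched against the `gene_id` column).
#' @return a `codon_usage`: named probability vector over the 64 codons.
#' @export
codon_usage <- function(aorfs, sequence, gene_ids = NULL) {
  df <- as.data.frame(aorfs)
  if (!is.null(gene_ids)) {
    if (is.null(df$gene_id)) stop("ORF set has no gene_id column")
    df <- df[df$gene_id %in% gene_ids, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no annotated ORFs to estimate codon usage from")
  stopifnot(all((df$end_bp - df$start_bp + 1L) %% 3L == 0L))
  codes <- seq_to_codes(sequence)
  counts <- numeric(64)
  for (i in seq_len(nrow(df))) {
    g <- codes[df$start_bp[i]:df$end_bp[i]]
    if (df$strand[i] == "-") g <- revcomp_codes(g)
    counts <- counts + tabulate(frame_codon_index(g, 0L), nbins = 64L)
  }
  if (sum(counts) == 0) stop("zero codons counted")
  as_codon_usage(counts, source = attr(aorfs, "source"))
}

#' Codon distribution of the antiparallel in-register frame (-1)
#'
#' @param usage a `codon_usage` for frame +1.
#' @return a `codon_usage` q with q(c) = usage(revcomp(c)).
#' @export
frame_minus1_usage <- function(usage) {
  p <- as_codon_usage(usage)
  q <- numeric(64)
  q[.rc_perm] <- unclass(p)
  as_codon_usage(q, source = attr(usage, "source"))
}

# position marginals of a usage, as arrays over nucleotide codes 0..3
usage_marginals <- function(p) {
  # CODONS order has the third codon position varying fastest; fill the
  # [pos1, pos2, pos3] array through explicit indices rather than dim().
  a <- (seq_len(64) - 1L) %/% 16L + 1L
  b <- ((seq_len(64) - 1L) %/% 4L) %% 4L + 1L
  c <- (seq_len(64) - 1L) %% 4L + 1L
  pi3 <- array(0, dim = c(4, 4, 4))
  pi3[cbind(a, b, c)] <- unclass(as_codon_usage(p))
  list(
    pi3 = pi3,                                  # pi3[a,b,c] = P(codon = abc)
    m1 = apply(pi3, 1, sum),                    # first-position marginal
    m3 = apply(pi3, 3, sum),                    # third-position marginal
    m12 = apply(pi3, c(1, 2), sum),             # first-two-position marginal
    m23 = apply(pi3, c(2, 3), sum)              # last-two-position marginal
  )
}

#' Transition matrix of a frame-shift Markov chain
#'
#' For frame +2 the chain's state is the triplet formed by the last two
#' nucleotides of one +1 codon and the first nucleotide of the next; for +3
#' it is the last nucleotide of one codon and the first two of the next.
#' Over IID +1 codons the transition law factorizes into a conditional part
#' and a marginal part: for +2,
#' `Q((a,b,c) -> (d,e,f)) = pi(c,d,e)/m1(c) * m1(f)` with `m1` the
#' first-position marginal of the usage; for +3,
#' `Q((a,b,c) -> (d,e,f)) = pi(b,c,d)/m12(b,c) * m12(e,f)`.  Frames -2 and
#' -3 use the same construction applied to [frame_minus1_usage()].  Rows of
#' states with zero reachable mass are set to the frame's unconditional
#' codon distribution so the matrix stays stochastic.
#'
#' @param usage a `codon_usage` (frame +1).
#' @param frame one of `"+2"`, `"+3"`, `"-2"`, `"-3"`.
#' @return 64 x 64 row-stochastic matrix with codon dimnames.
#' @export
transition_matrix <- function(usage, frame = c("+2", "+3", "-2", "-3")) {
  frame <- match.arg(frame)
  p <- if (frame %in% c("-2", "-3")) frame_minus1_usage(usage) else as_codon_usage(usage)
  mg <- usage_marginals(p)
  a <- (seq_len(64) - 1L) %/% 16L + 1L
  b <- ((seq_len(64) - 1L) %/% 4L) %% 4L + 1L
  c <- (seq_len(64) - 1L) %% 4L + 1L
  Q <- matrix(0, 64, 64, dimnames = list(CODONS, CODONS))
  if (frame %in% c("+2", "-2")) {
    cond <- mg$m1[c]                           # conditioning value per row
    # column factor: pi(c_row, d, e) * m1(f) / m1(c_row)
    for (row in seq_len(64)) {
      if (cond[row] > 0) {
        Q[row, ] <- mg$pi3[cbind(c[row], a, b)] / cond[row] * mg$m1[c]
      }
    }
    uncond <- mg$m23[cbind(a, b)] * mg$m1[c]   # stationary marginal of the frame
    reach <- mg$m23[cbind(a, b)] > 0 & mg$m1[c] > 0
  } else {
    cond <- mg$m12[cbind(b, c)]
    for (row in seq_len(64)) {
      if (cond[row] > 0) {
        Q[row, ] <- mg$pi3[cbind(b[row], c[row], a)] / cond[row] * mg$m12[cbind(b, c)]
      }
    }
    uncond <- mg$m3[a] * mg$m12[cbind(b, c)]
    reach <- mg$m3[a] > 0 & mg$m12[cbind(b, c)] > 0
  }
  rs <- rowSums(Q)
  dead <- rs < .Machine$double.eps * 64
  if (any(dead & reach)) {
    stop("degenerate usage: zero conditioning marginal for reachable state(s) ",
         paste(CODONS[dead & reach], collapse = ", "))
  }
  if (any(dead)) {
    s <- sum(uncond)
    if (s <= 0) stop("degenerate usage: no reachable state in frame ", frame)
    Q[dead, ] <- matrix(uncond / s, sum(dead), 64, byrow = TRUE)
    rs[dead] <- 1
  }
  Q / rs
}

# communicating classes of the positivity graph; returns list of index sets
# that are *closed* (no transition leaves the class)
closed_classes <- function(Q) {
  A <- Q > 0
  diag(A) <- TRUE
  R <- A
  for (k in 1:6) R <- (R %*% R) > 0                 # transitive closure, 2^6 >= 64
  cls <- unique(apply(R & t(R), 1, function(z) which(z), simplify = FALSE))
  Filter(function(idx) {
    out <- which(colSums(Q[idx, , drop = FALSE] > 0) > 0)
    all(out %in% idx)
  }, cls)
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Solved directly as the linear system `(t(Q) - I) d = 0` with the
#' normalization `sum(d) = 1` appended; power iteration is the fallback for
#' an ill-conditioned solve.  A chain with more than one closed
#' communicating class has no unique stationary law and raises an error
#' naming the classes.
#'
#' @param matrix 64 x 64 (or any square) row-stochastic matrix.
#' @return stationary probability vector `d` with `d %*% matrix = d`.
#' @export
stationary_distribution <- function(matrix) {
  n <- nrow(matrix)
  stopifnot(ncol(matrix) == n, all(matrix >= 0),
            max(abs(rowSums(matrix) - 1)) < 1e-9)
  cc <- closed_classes(matrix)
  if (length(cc) > 1L) {
    labs <- vapply(cc, function(idx) {
      nm <- if (!is.null(rownames(matrix))) rownames(matrix)[idx] else idx
      paste0("{", paste(nm, collapse = ","), "}")
    }, character(1L))
    stop("chain is reducible with ", length(cc), " closed classes: ",
         paste(labs, collapse = " "))
  }
  A <- rbind(t(matrix) - diag(n), rep(1, n))
  b <- c(rep(0, n), 1)
  d <- tryCatch(as.vector(qr.solve(A, b)), error = function(e) NULL)
  if (is.null(d) || min(d) < -1e-8 ||
      max(abs(as.vector(d %*% matrix) - d)) > 1e-12) {
    d <- rep(1 / n, n)                              # power-iteration fallback
    for (it in seq_len(1e5)) {
      d2 <- as.vector(d %*% matrix)
      if (max(abs(d2 - d)) < 1e-14) { d <- d2; break }
      d <- d2
    }
  }
  d[d < 0] <- 0
  d <- d / sum(d)
  stats::setNames(d, rownames(matrix))
}

#' Start/stop codon probabilities for all six relative reading frames
#'
#' Frames +1 and -1 take their codon distributions directly from the usage
#' and its reverse-complement transform; frames +2, +3, -2 and -3 take
#' theirs from the stationary distributions of the corresponding frame-shift
#' chains.  The stop probability `rho_i` is the stationary mass on the stop
#' set, the start probability `tau_i` the mass on the start set.
#'
#' @param usage a `codon_usage`.
#' @param code a [genetic_code_config()].
#' @return a `frame_probabilities` object: data frame with columns `frame`,
#'   `rho`, `tau` plus a `distributions` attribute holding the six per-frame
#'   codon distributions.
#' @export
frame_probabilities <- function(usage, code = genetic_code_config()) {
  usage <- as_codon_usage(usage)
  stopifnot(inherits(code, "genetic_code_config"))
  dists <- list(
    "+1" = stats::setNames(as.numeric(usage), CODONS),
    "+2" = stationary_distribution(transition_matrix(usage, "+2")),
    "+3" = stationary_distribution(transition_matrix(usage, "+3")),
    "-1" = stats::setNames(as.numeric(frame_minus1_usage(usage)), CODONS),
    "-2" = stationary_distribution(transition_matrix(usage, "-2")),
    "-3" = stationary_distribution(transition_matrix(usage, "-3"))
  )
  si <- codon_index(code$stop_set)
  ti <- codon_index(code$start_set)
  fp <- data.frame(
    frame = names(dists),
    rho = vapply(dists, function(d) sum(d[si]), numeric(1L)),
    tau = vapply(dists, function(d) sum(d[ti]), numeric(1L)),
    stringsAsFactors = FALSE
  )
  rownames(fp) <- fp$frame
  if (any(fp$rho == 0)) {
    warning("stop probability is 0 in frame(s) ",
            paste(fp$frame[fp$rho == 0], collapse = ", "),
            "; survival probabilities degenerate")
  }
  structure(fp, class = c("frame_probabilities", "data.frame"),
            distributions = dists, code = code, source = attr(usage, "source"))
}

#' Read / write a codon usage as a 64-row TSV (codon, probability)
#'
#' @param usage a `codon_usage`.
#' @param path file path.
#' @return `write_usage_tsv`: `path` invisibly; `read_usage_tsv`: a
#'   `codon_usage`.
#' @export
write_usage_tsv <- function(usage, path) {
  usage <- as_codon_usage(usage)
  utils::write.table(
    data.frame(codon = CODONS, probability = unclass(usage)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_usage_tsv
#' @export
read_usage_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("codon", "probability") %in% names(df)))
  as_codon_usage(stats::setNames(df$probability, df$codon),
                 source = basename(path))
}
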