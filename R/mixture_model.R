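## The analytical ORF-length model: a six-component geometric mixture.
##
## Within one relative reading frame i a codon position is inside an ORF or
## between two ORFs; entering happens on a start codon (probability tau_i),
## leaving on a stop codon (probability rho_i).  The stationary law of this
## two-state chain gives the in-ORF fraction alpha_i = tau_i/(tau_i + rho_i);
## dividing the in-ORF codon mass by the expected dwell 1/rho_i yields the
## expected ORF count N_i = n_i * tau_i * rho_i / (tau_i + rho_i) for n_i
## codon positions.  ORF lengths in frame i are geometric on {1, 2, ...}
## codons (start codon counted, stop codon excluded), and the genome-wide
## length law is the mixture with weights w_i = N_i / sum(N_j).

FRAMES <- c("+1", "+2", "+3", "-1", "-2", "-3")

#' Build the six-frame geometric mixture model
#'
#' @param fp a [frame_probabilities()] object.
#' @param genome_bp genome length in bp; each frame contributes
#'   `n_i = floor(genome_bp/3)` codon positions.
#' @param tail_exponent_offset exponent offset of the geometric tail,
#'   `P(L >= l) = (1-rho)^(l + offset)`; the default -1 is the exact tail of
#'   the geometric law on support \{1, 2, ...\}.
#' @return an `orf_mixture`: data frame `frames` (columns `frame`, `rho`,
#'   `tau`, `alpha`, `n_codons`, `N`, `w`) plus fields `genome_bp`, `N`
#'   (total expected ORF count) and `code`.
#' @export
build_model <- function(fp, genome_bp, tail_exponent_offset = -1L) {
  stopifnot(inherits(fp, "frame_probabilities"), genome_bp >= 3)
  f <- as.data.frame(fp)[FRAMES, ]
  stopifnot(all(f$rho + f$tau > 0), all(f$rho > 0 & f$rho < 1),
            all(f$tau > 0 & f$tau < 1))
  n_i <- genome_bp %/% 3
  f$alpha <- f$tau / (f$tau + f$rho)
  f$n_codons <- n_i
  f$N <- n_i * f$tau * f$rho / (f$tau + f$rho)
  f$w <- f$N / sum(f$N)
  structure(
    list(frames = f, genome_bp = genome_bp, N = sum(f$N),
         code = attr(fp, "code"), tail_exponent_offset = tail_exponent_offset,
         source = attr(fp, "source")),
    class = "orf_mixture"
  )
}

#' @export
print.orf_mixture <- function(x, ...) {
  cat("<orf_mixture> ", x$genome_bp, " bp",
      if (!is.null(x$source) && !is.na(x$source)) paste0(" (", x$source, ")"),
      ": expected ", round(x$N), " ORFs, mean length ",
      round(average_orf_length(x), 2), " codons\n", sep = "")
  print(round(x$frames[, c("rho", "tau", "alpha", "N", "w")], 6))
  invisible(x)
}

#' Mixture probability of observing an ORF of exactly l codons
#'
#' `P(L = l) = sum_i w_i (1-rho_i)^(l-1) rho_i` on support l = 1, 2, ....
#'
#' @param model an `orf_mixture`.
#' @param l ORF length(s) in codons (start counted, stop excluded).
#' @return probability vector of the same length as `l`.
#' @export
length_pmf <- function(model, l) {
  stopifnot(inherits(model, "orf_mixture"), all(l >= 1))
  f <- model$frames
  sapply(l, function(li) sum(f$w * (1 - f$rho)^(li - 1) * f$rho))
}

#' Mixture tail probability P(L >= l)
#'
#' `P(L >= l) = sum_i w_i (1-rho_i)^(l-1)`, the geometric-series closed form
#' of summing [length_pmf()] from `l` upward.
#'
#' @inheritParams length_pmf
#' @return probability vector.
#' @export
tail_probability <- function(model, l) {
  stopifnot(inherits(model, "orf_mixture"), all(l >= 1))
  f <- model$frames
  sapply(l, function(li) sum(f$w * (1 - f$rho)^(li - 1)))
}

# per-frame geometric tail with the model's exponent convention
frame_tail <- function(model, frame, l) {
  rho <- model$frames[frame, "rho"]
  (1 - rho)^(l + model$tail_exponent_offset)
}

#' Survival probability of long ORFs
#'
#' Probability of observing at least one ORF of length >= `l` codons among
#' `trials` independent draws from the mixture:
#' `S = 1 - (1 - P(L >= l))^trials`.  Used as a p-value against the
#' random-genome null.  The per-frame variant uses the frame-specific
#' geometric tail and expected count `N_i`.
#'
#' @param model an `orf_mixture`.
#' @param l length threshold in codons.
#' @param trials number of ORF draws; defaults to the model's total expected
#'   count `N` rounded to the nearest integer.
#' @param frame optional frame label (`"+2"`, `"-1"`, ...) for the per-frame
#'   variant; `trials` then defaults to that frame's `N_i`.
#' @param continuous if `TRUE`, use the fractional expected count as the
#'   exponent instead of rounding.
#' @return a `survival_result` data frame with columns `l`, `tail`
#'   (`P(L >= l)`), `trials` and `survival`.
#' @export
orf_survival <- function(model, l, trials = NULL, frame = NULL,
                         continuous = FALSE) {
  stopifnot(inherits(model, "orf_mixture"), all(l >= 1))
  if (is.null(frame)) {
    tl <- tail_probability(model, l)
    ntr <- if (is.null(trials)) model$N else trials
  } else {
    stopifnot(frame %in% FRAMES)
    tl <- frame_tail(model, frame, l)
    ntr <- if (is.null(trials)) model$frames[frame, "N"] else trials
  }
  if (!continuous) ntr <- round(ntr)
  stopifnot(ntr >= 0)
  res <- data.frame(l = l, tail = tl, trials = ntr,
                    survival = 1 - (1 - tl)^ntr)
  class(res) <- c("survival_result", "data.frame")
  res
}

#' Length limit at a given p-value
#'
#' The smallest length `l` (codons) whose survival probability does not
#' exceed `pvalue`; found by bisection, since the survival probability is
#' non-increasing in `l`.
#'
#' @param model an `orf_mixture`.
#' @param pvalue significance level in (0, 1).
#' @param frame optional frame label for the per-frame variant.
#' @return length limit in codons (integer).
#' @export
survival_limit <- function(model, pvalue, frame = NULL) {
  stopifnot(pvalue > 0, pvalue < 1)
  surv <- function(l) orf_survival(model, l, frame = frame)$survival
  lo <- 1
  hi <- 2
  while (surv(hi) > pvalue) {
    lo <- hi
    hi <- hi * 2
    if (hi > 1e9) stop("survival limit beyond 1e9 codons")
  }
  if (surv(lo) <= pvalue) return(as.integer(lo))
  while (hi - lo > 1) {               # invariant: surv(lo) > p >= surv(hi)
    mid <- (lo + hi) %/% 2
    if (surv(mid) <= pvalue) hi <- mid else lo <- mid
  }
  as.integer(hi)
}

#' Expected average ORF length of the model
#'
#' `sum_i w_i / rho_i` codons — depends only on the start and stop codon
#' probabilities, not on the genome length.
#'
#' @param model an `orf_mixture`.
#' @return expected length in codons.
#' @export
average_orf_length <- function(model) {
  stopifnot(inherits(model, "orf_mixture"))
  sum(model$frames$w / model$frames$rho)
}

#' Length quantile of the mixture
#'
#' Smallest `l` with `P(L <= l) >= p` (inverse of the tail), by bisection.
#'
#' @param model an `orf_mixture`.
#' @param p probability level(s) in (0, 1).
#' @return quantile(s) in codons.
#' @export
length_quantile <- function(model, p) {
  stopifnot(all(p > 0), all(p < 1))
  vapply(p, function(pi) {
    lo <- 0; hi <- 1
    while (1 - tail_probability(model, hi + 1) < pi) hi <- hi * 2
    while (hi - lo > 1) {
      mid <- (lo + hi) %/% 2
      if (1 - tail_probability(model, mid + 1) >= pi) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1L))
}

#' Expected ORF-length histogram
#'
#' `count(l) = N * P(L = l)` for l = 1..`l_max`; the per-frame variant uses
#' `N_i` and the frame-i geometric pmf.
#'
#' @param model an `orf_mixture`.
#' @param l_max largest length (codons) to tabulate.
#' @param frame optional frame label for the per-frame variant.
#' @return data frame with columns `l` and `expected`.
#' @export
expected_histogram <- function(model, l_max, frame = NULL) {
  stopifnot(l_max >= 1)
  l <- seq_len(l_max)
  if (is.null(frame)) {
    data.frame(l = l, expected = model$N * length_pmf(model, l))
  } else {
    stopifnot(frame %in% FRAMES)
    rho <- model$frames[frame, "rho"]
    data.frame(l = l, expected = model$frames[frame, "N"] *
                 (1 - rho)^(l - 1) * rho)
  }
}

#' Predicted number of genes
#'
#' The model's expected count of frame +1 ORFs, optionally restricted to
#' ORFs of at least `min_len` codons via the frame +1 geometric tail.
#'
#' @param model an `orf_mixture`.
#' @param min_len optional minimal gene length in codons.
#' @return expected gene count.
#' @export
predicted_gene_count <- function(model, min_len = NULL) {
  stopifnot(inherits(model, "orf_mixture"))
  N1 <- model$frames["+1", "N"]
  if (is.null(min_len)) return(N1)
  stopifnot(min_len >= 1)
  N1 * frame_tail(model, "+1", min_len)
}

#' Serialize / deserialize a mixture model as JSON
#'
#' @param model an `orf_mixture`.
#' @param path file path.
#' @return `model_to_json`: `path` invisibly; `model_from_json`: an
#'   `orf_mixture`.
#' @export
model_to_json <- function(model, path) {
  f <- model$frames
  obj <- list(
    frames = stats::setNames(lapply(seq_len(nrow(f)), function(i) {
      list(rho = f$rho[i], tau = f$tau[i], alpha = f$alpha[i],
           N = f$N[i], w = f$w[i])
    }), f$frame),
    genome_bp = model$genome_bp,
    code = list(start_set = model$code$start_set,
                stop_set = model$code$stop_set),
    tail_exponent_offset = model$tail_exponent_offset,
    source = if (is.null(model$source)) NA else model$source
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  fr <- names(obj$frames)
  f <- data.frame(
    frame = fr,
    rho = vapply(obj$frames, function(x) x$rho, numeric(1L)),
    tau = vapply(obj$frames, function(x) x$tau, numeric(1L)),
    alpha = vapply(obj$frames, function(x) x$alpha, numeric(1L)),
    n_codons = obj$genome_bp %/% 3,
    N = vapply(obj$frames, function(x) x$N, numeric(1L)),
    w = vapply(obj$frames, function(x) x$w, numeric(1L)),
    stringsAsFactors = FALSE
  )
  rownames(f) <- f$frame
  structure(
    list(frames = f[FRAMES, ], genome_bp = obj$genome_bp, N = sum(f$N),
         code = genetic_code_config(
           stop_set = unlist(obj$code$stop_set),
           start_set = unlist(obj$code$start_set)
         ),
         tail_exponent_offset = obj$tail_exponent_offset,
         source = obj$source),
    class = "orf_mixture"
  )
}
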