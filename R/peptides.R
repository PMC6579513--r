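#' Peptide table constructor and validator
#'
#' A peptide table is the unit map of an HDX-MS experiment: one row per
#' peptic peptide ion with its sequence, construct-numbered span and charge
#' state. Peptides observed at different charge states are distinct rows
#' (the percent-deuterium formula is charge-invariant, but ions are tracked
#' separately as in conventional HDX reporting, labelled
#' \code{"start-end (charge)"}).
#'
#' @param x data.frame with columns \code{id}, \code{sequence},
#'   \code{start}, \code{end}, \code{charge}.
#' @return the validated data.frame with class \code{hdx_peptides} and a
#'   \code{label} column added.
#' @export
hdx_peptides <- function(x) {
  x <- as.data.frame(x)
  need <- c("id", "sequence", "start", "end", "charge")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("peptide table missing column(s): ",
                         paste(miss, collapse = ", "))
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  x$charge <- as.integer(x$charge)
  x$sequence <- toupper(as.character(x$sequence))
  if (any(x$charge < 1L)) stop("charge must be >= 1")
  if (any(!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x$sequence)))
    stop("peptide sequences must use the 20 standard amino-acid letters")
  bad <- which(x$end - x$start + 1L != nchar(x$sequence))
  if (length(bad))
    stop("span/sequence length mismatch for peptide(s): ",
         paste(x$id[bad], collapse = ", "))
  if (anyDuplicated(x$id)) stop("peptide ids must be unique")
  x$label <- sprintf("%d-%d (%d)", x$start, x$end, x$charge)
  class(x) <- c("hdx_peptides", "data.frame")
  x
}

#' Number of exchangeable residues of a peptide
#'
#' In centroid-based HDX the first two residues of each peptide do not
#' retain deuterium (fast back-exchange of the N-terminal amides) and
#' prolines carry no backbone amide hydrogen, so both are omitted from all
#' calculations. The exchangeable count is therefore the number of
#' non-proline residues at peptide positions >= 3.
#'
#' @param sequence peptide amino-acid string (vectorised).
#' @return integer vector; 0 for peptides shorter than 3 residues (callers
#'   decide whether to drop such peptides).
#' @export
exchangeable_residue_count <- function(sequence) {
  vapply(as.character(sequence), function(s) {
    if (nchar(s) < 3L) return(0L)
    body <- substring(s, 3L)
    nchar(body) - sum(strsplit(body, "")[[1]] == "P")
  }, integer(1), USE.NAMES = FALSE)
}

#' Construct-numbered exchangeable residues of one peptide
#'
#' @param start,end inclusive construct-numbered span.
#' @param sequence the peptide sequence (used to locate prolines).
#' @return integer vector of residue numbers contributing exchange signal.
#' @export
exchangeable_residues <- function(start, end, sequence) {
  if (end - start + 1L != nchar(sequence))
    stop("span/sequence length mismatch")
  if (nchar(sequence) < 3L) return(integer(0))
  pos <- 3:nchar(sequence)
  chars <- strsplit(sequence, "")[[1]][pos]
  (start + pos - 1L)[chars != "P"]
}

#' Percent sequence coverage of a peptide map
#'
#' Coverage is reported on full peptide spans (the convention of coverage
#' maps), not on the exchangeable subsets used for consolidation.
#'
#' @param peptides an [hdx_peptides()] table (or coercible data.frame).
#' @param seq_length construct length in residues.
#' @param first_index construct number of the first residue.
#' @return coverage percentage in [0, 100].
#' @export
sequence_coverage <- function(peptides, seq_length, first_index = 1L) {
  peptides <- as.data.frame(peptides)
  last <- first_index + seq_length - 1L
  if (any(peptides$start < first_index) || any(peptides$end > last))
    stop("peptide span outside the construct")
  covered <- rep(FALSE, seq_length)
  for (j in seq_len(nrow(peptides))) {
    covered[(peptides$start[j]:peptides$end[j]) - first_index + 1L] <- TRUE
  }
  100 * sum(covered) / seq_length
}

#' Generate an overlapping peptic-peptide map
#'
#' Emulates the peptide map an in-line pepsin digest typically yields:
#' overlapping peptides of variable length whose union covers most but not
#' all of the sequence. Uncovered stretches are planted explicitly so the
#' union coverage lands on the target; within each covered segment peptide
#' starts are spread evenly with jitter and lengths drawn around
#' \code{mean_length}, then extended minimally where needed so no internal
#' gap opens. The default preset on a 254-residue construct yields 54
#' peptides at ~98\% coverage.
#'
#' @param protein an \code{hdx_protein} (source of sequence and numbering).
#' @param n_peptides number of peptides to place.
#' @param target_coverage union coverage fraction in (0, 1].
#' @param mean_length mean peptide length (>= 4); lengths are clamped to
#'   \code{[min_length, max_length]}.
#' @param min_length,max_length hard bounds on peptide length.
#' @param seed integer seed; the map is fully determined by it.
#' @return an \code{hdx_peptides} table.
#' @export
generate_peptide_map <- function(protein, n_peptides = 54L,
                                 target_coverage = 0.98, mean_length = 12,
                                 min_length = 5L, max_length = 24L,
                                 seed = 1L) {
  stopifnot(inherits(protein, "hdx_protein"))
  if (target_coverage <= 0 || target_coverage > 1)
    stop("target_coverage must be in (0, 1]")
  if (mean_length < 4) stop("mean_length must be >= 4")
  set.seed(as.integer(seed))
  L <- nchar(protein$sequence)
  n_cov <- round(target_coverage * L)
  if (n_peptides * max_length < n_cov)
    stop("coverage unreachable: ", n_peptides, " peptides of at most ",
         max_length, " residues cannot cover ", n_cov, " residues")
  gap_total <- L - n_cov
  # plant interior gaps (1-3 stretches) so union coverage hits the target
  segments <- list(c(1L, L))
  if (gap_total > 0L) {
    n_gaps <- min(3L, max(1L, round(gap_total / 3)))
    sizes <- diff(round(seq(0, gap_total, length.out = n_gaps + 1L)))
    sizes <- sizes[sizes > 0L]
    gap_starts <- sort(sample(seq(10L, L - 10L - max(sizes)),
                              length(sizes)))
    # keep gaps disjoint and ordered
    for (k in seq_along(gap_starts)[-1]) {
      lo <- gap_starts[k - 1L] + sizes[k - 1L] + min_length
      if (gap_starts[k] < lo) gap_starts[k] <- lo
    }
    bounds <- c(1L, as.vector(rbind(gap_starts - 1L,
                                    gap_starts + sizes)), L)
    segments <- lapply(seq_len(length(bounds) / 2L),
                       function(i) c(bounds[2L * i - 1L], bounds[2L * i]))
  }
  segments <- lapply(segments, as.integer)
  seg_len <- vapply(segments, function(s) s[2] - s[1] + 1L, integer(1))
  if (any(seg_len < min_length))
    stop("infeasible gap layout; lower target_coverage or n_peptides")
  # apportion peptides to segments: each gets what it minimally needs
  # to be coverable, the rest goes out proportionally to length
  need <- pmax(1L, as.integer(ceiling(seg_len / max_length)))
  if (sum(need) > n_peptides)
    stop("coverage unreachable: the gap layout needs at least ",
         sum(need), " peptides")
  n_seg <- need
  leftover <- n_peptides - sum(need)
  if (leftover > 0L) {
    quota <- leftover * seg_len / sum(seg_len)
    extra <- floor(quota)
    rem <- leftover - sum(extra)
    if (rem > 0) {
      o <- order(quota - extra, decreasing = TRUE)
      extra[o[seq_len(rem)]] <- extra[o[seq_len(rem)]] + 1L
    }
    n_seg <- n_seg + as.integer(extra)
  }
  first <- protein$first_index
  rows <- list()
  for (si in seq_along(segments)) {
    s0 <- segments[[si]][1]; s1 <- segments[[si]][2]
    k <- n_seg[si]
    slen <- s1 - s0 + 1L
    if (k * max_length < slen)
      stop("coverage unreachable within a segment; raise n_peptides")
    if (k == 1L) {
      starts <- s0
    } else {
      starts <- round(seq(s0, s1 - min_length + 1L, length.out = k))
      jit <- sample(-2:2, k, replace = TRUE)
      starts <- pmin(pmax(starts + jit, s0), s1 - min_length + 1L)
      starts <- sort(starts); starts[1] <- s0
    }
    lens <- pmin(pmax(round(stats::rnorm(k, mean_length, 3)),
                      min_length), max_length)
    ends <- pmin(starts + lens - 1L, s1)
    # close internal gaps by minimal extension; guarantee segment coverage
    for (j in seq_len(k)) {
      need <- if (j < k) starts[j + 1L] - 1L else s1
      if (ends[j] < need && (j == k || starts[j + 1L] > ends[j] + 1L)) {
        ends[j] <- min(need, starts[j] + max_length - 1L)
      }
      if (j < k && starts[j + 1L] > ends[j] + 1L)
        starts[j + 1L] <- ends[j] + 1L
    }
    if (ends[k] < s1) ends[k] <- s1
    if (ends[k] - starts[k] + 1L > max_length)
      starts[k] <- ends[k] - max_length + 1L
    rows[[si]] <- data.frame(start = starts + first - 1L,
                             end = ends + first - 1L)
  }
  pep <- do.call(rbind, rows)
  pep <- pep[order(pep$start, pep$end), , drop = FALSE]
  pep$charge <- sample(1:3, nrow(pep), replace = TRUE,
                       prob = c(0.25, 0.55, 0.20))
  pep$sequence <- substring(protein$sequence,
                            pep$start - first + 1L,
                            pep$end - first + 1L)
  pep$id <- sprintf("P%03d", seq_len(nrow(pep)))
  hdx_peptides(pep[, c("id", "sequence", "start", "end", "charge")])
}
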