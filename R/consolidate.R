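#' Consolidate overlapping peptide values to per-residue values
#'
#' Residue averaging: each residue's value is a weighted mean over the
#' peptides whose exchangeable residues contain it, with shorter peptides
#' weighted more heavily (they localise the signal better). The default
#' weight is the inverse exchangeable-residue count,
#' \eqn{w_j = 1 / n_{ex,j}}; any positive monotone-decreasing weight
#' function of the exchangeable count can be plugged in. The first two
#' residues of each peptide and all prolines never receive contributions
#' from that peptide. Residues no peptide covers are missing (never zero).
#'
#' @param values named numeric vector: peptide id -> value (percent D or
#'   delta percent D).
#' @param peptides an [hdx_peptides()] table containing those ids.
#' @param seq_length construct length; defaults to the span of the
#'   peptide table.
#' @param first_index construct number of the first residue.
#' @param weight_fun function of the exchangeable-residue count returning
#'   a positive weight; default \code{function(n) 1 / n}.
#' @return data.frame of class \code{hdx_residue_map} with columns
#'   \code{residue}, \code{value}, \code{depth}, \code{missing}.
#' @export
consolidate_to_residues <- function(values, peptides, seq_length = NULL,
                                    first_index = NULL,
                                    weight_fun = function(n) 1 / n) {
  peptides <- as.data.frame(peptides)
  if (is.null(names(values)))
    stop("values must be named by peptide id")
  miss <- setdiff(names(values), peptides$id)
  if (length(miss)) stop("values for unknown peptide(s): ",
                         paste(miss, collapse = ", "))
  pep <- peptides[match(names(values), peptides$id), ]
  if (is.null(first_index)) first_index <- min(pep$start)
  if (is.null(seq_length)) seq_length <- max(pep$end) - first_index + 1L
  n_ex <- exchangeable_residue_count(pep$sequence)
  if (any(n_ex == 0L & !is.na(values)))
    stop("valued peptide(s) with no exchangeable residues: ",
         paste(pep$id[n_ex == 0L & !is.na(values)], collapse = ", "))
  num <- den <- rep(0, seq_length)
  depth <- rep(0L, seq_length)
  for (j in seq_len(nrow(pep))) {
    if (is.na(values[j])) next
    res <- exchangeable_residues(pep$start[j], pep$end[j],
                                 pep$sequence[j])
    i <- res - first_index + 1L
    w <- weight_fun(n_ex[j])
    if (!is.finite(w) || w <= 0) stop("weight function must be positive")
    num[i] <- num[i] + w * values[j]
    den[i] <- den[i] + w
    depth[i] <- depth[i] + 1L
  }
  value <- ifelse(den > 0, num / den, NA_real_)
  out <- data.frame(residue = first_index:(first_index + seq_length - 1L),
                    value = value, depth = depth, missing = den == 0)
  class(out) <- c("hdx_residue_map", "data.frame")
  out
}

#' @export
print.hdx_residue_map <- function(x, ...) {
  cat(sprintf("Residue map: %d residues (%d-%d), %d covered (%.1f%%), depth up to %d\n",
              nrow(x), min(x$residue), max(x$residue), sum(!x$missing),
              100 * mean(!x$missing), max(x$depth)))
  if (any(!x$missing))
    cat(sprintf("  consolidated values in [%.2f, %.2f]\n",
                min(x$value, na.rm = TRUE), max(x$value, na.rm = TRUE)))
  invisible(x)
}

#' Plot a consolidated residue map
#'
#' Per-residue consolidated value along the sequence, with uncovered
#' residues left blank.
#'
#' @param x an \code{hdx_residue_map}.
#' @param ... passed to [graphics::plot()].
#' @export
plot.hdx_residue_map <- function(x, ...) {
  graphics::plot(x$residue, x$value, type = "h", xlab = "residue",
                 ylab = "consolidated value", ...)
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' Export a residue/value attribute list
#'
#' Two-column table (residue, value) of the covered residues, suitable for
#' substitution into the B-factor column of a coordinate file by external
#' tools.
#'
#' @param map an \code{hdx_residue_map}.
#' @param path output path (CSV without header, \code{residue,value}).
#' @return the written data.frame, invisibly.
#' @export
write_attribute_list <- function(map, path) {
  d <- map[!map$missing, c("residue", "value")]
  utils::write.table(d, path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(d)
}
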