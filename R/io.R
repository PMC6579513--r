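# canonical uptake-table schema and a shim for common export spellings
.uptake_aliases <- c(
  peptide_id = "peptide_id", peptide = "peptide_id", pep_id = "peptide_id",
  sequence = "sequence", peptide_sequence = "sequence",
  start = "start", start_res = "start", "from" = "start",
  end = "end", end_res = "end", "to" = "end",
  charge = "charge", z = "charge", charge_state = "charge",
  condition = "condition", sample = "condition", state = "condition",
  timepoint_s = "timepoint_s", timepoint = "timepoint_s",
  exposure = "timepoint_s", exposure_s = "timepoint_s",
  time_s = "timepoint_s",
  replicate = "replicate", rep = "replicate",
  percent_d = "percent_d", percentd = "percent_d", pct_d = "percent_d",
  deut_percent = "percent_d",
  undeut_mz = "undeut_mz", obs_mz = "obs_mz", dmax_mz = "dmax_mz")

.map_columns <- function(nms) {
  key <- gsub("[^a-z0-9_]", "_", tolower(nms))
  mapped <- .uptake_aliases[key]
  ifelse(is.na(mapped), nms, mapped)
}

.check_numeric <- function(x, col, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & x != "")
  if (length(bad))
    stop("non-numeric value in column '", col, "' of ", path,
         " at data row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  v
}

#' Read an uptake table
#'
#' Reads the long CSV dialect of per-replicate uptake observations
#' (columns \code{peptide_id}, \code{sequence}, \code{start}, \code{end},
#' \code{charge}, \code{condition}, \code{timepoint_s}, \code{replicate}
#' and either \code{percent_d} or the centroid triple \code{undeut_mz},
#' \code{obs_mz}, \code{dmax_mz}). Common HDX-Workbench-style column
#' spellings are mapped onto this schema. When centroid columns are
#' present, percent deuterium is computed on the fly via
#' [percent_deuterium()]. Schema and value errors are reported with
#' column names and row numbers.
#'
#' @param path CSV file path.
#' @return list with \code{observations} (validated long data.frame,
#'   class \code{hdx_uptake}) and \code{peptides} (an
#'   [hdx_peptides()] table).
#' @export
read_uptake_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(d) <- .map_columns(names(d))
  need <- c("peptide_id", "sequence", "start", "end", "charge",
            "condition", "timepoint_s", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("uptake table ", path, " missing required column(s): ",
         paste(miss, collapse = ", "))
  centroid_mode <- all(c("undeut_mz", "obs_mz", "dmax_mz") %in% names(d))
  if (!centroid_mode && !"percent_d" %in% names(d))
    stop("uptake table ", path,
         " needs a percent_d column or centroid columns ",
         "undeut_mz/obs_mz/dmax_mz")
  for (col in c("start", "end", "charge", "timepoint_s", "replicate"))
    d[[col]] <- .check_numeric(d[[col]], col, path)
  if (centroid_mode) {
    for (col in c("undeut_mz", "obs_mz", "dmax_mz"))
      d[[col]] <- .check_numeric(d[[col]], col, path)
    d$percent_d <- percent_deuterium(d$undeut_mz, d$obs_mz, d$dmax_mz)
  } else {
    d$percent_d <- .check_numeric(d$percent_d, "percent_d", path)
  }
  bad <- which(d$end - d$start + 1L != nchar(d$sequence))
  if (length(bad))
    stop("sequence/span mismatch in ", path, " at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (any(d$timepoint_s < 0)) stop("negative timepoint in ", path)
  pep <- unique(d[, c("peptide_id", "sequence", "start", "end",
                      "charge")])
  names(pep)[1] <- "id"
  pep <- hdx_peptides(pep[!duplicated(pep$id), ])
  obs <- d[, c("peptide_id", "sequence", "start", "end", "charge",
               "condition", "timepoint_s", "replicate", "percent_d")]
  class(obs) <- c("hdx_uptake", "data.frame")
  list(observations = obs, peptides = pep)
}

# numeric columns are written with 6 significant digits
.write_csv <- function(d, path) {
  num <- vapply(d, is.numeric, logical(1)) &
    !vapply(d, is.integer, logical(1))
  d[num] <- lapply(d[num], function(x) signif(x, 6))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an uptake table
#'
#' @param observations long uptake data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_uptake_table <- function(observations, path) {
  .write_csv(as.data.frame(observations), path)
}

.known_assays <- c("alphascreen", "thermal_shift", "cell_reporter")

#' Read a compound activity table
#'
#' CSV with columns \code{compound}, \code{assay}, \code{value}; assays
#' must be among \code{alphascreen} (RLU), \code{thermal_shift}
#' (delta Tm, degrees C) and \code{cell_reporter} (fold change). One value
#' per compound per assay.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_activity_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("compound", "assay", "value"), names(d))
  if (length(miss))
    stop("activity table ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(d) == 0L) {
    warning("activity table ", path, " is empty")
    return(d)
  }
  unknown <- setdiff(unique(d$assay), .known_assays)
  if (length(unknown))
    stop("unknown assay(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  d$value <- .check_numeric(d$value, "value", path)
  dup <- duplicated(d[, c("compound", "assay")])
  if (any(dup))
    stop("duplicate (compound, assay) pair(s) in ", path, ": ",
         paste(unique(paste(d$compound[dup], d$assay[dup])),
               collapse = "; "))
  d
}

#' Write a compound activity table
#' @param activities data.frame with compound, assay, value.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_activity_table <- function(activities, path) {
  .write_csv(as.data.frame(activities), path)
}

#' Read a construct sequence from FASTA
#'
#' The first record is used. A construct numbering offset may be encoded
#' in the header as \code{first_index=<n>} (otherwise supply it).
#'
#' @param path FASTA file.
#' @param first_index construct number of the first residue; overrides
#'   any header annotation.
#' @return list with \code{sequence}, \code{name}, \code{first_index}.
#' @export
read_fasta_sequence <- function(path, first_index = NULL) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE)
  if (length(recs) == 0L) stop("no sequences in ", path)
  seq <- toupper(as.character(recs[[1]]))
  header <- attr(recs[[1]], "Annot")
  if (is.null(first_index)) {
    m <- regmatches(header, regexpr("first_index=([0-9]+)", header))
    first_index <- if (length(m)) {
      as.integer(sub("first_index=", "", m))
    } else 1L
  }
  list(sequence = seq, name = attr(recs[[1]], "name"),
       first_index = as.integer(first_index))
}

#' Write perturbation results as CSV
#'
#' Emits the long record table (compound, peptide, timepoint, delta, t,
#' p, adjusted p, significant) and the wide compound x peptide-timepoint
#' delta matrix.
#'
#' @param pm an [perturbation_matrix()].
#' @param long_path,wide_path output CSV paths (either may be NULL).
#' @return invisible list of written paths.
#' @export
write_perturbation_tables <- function(pm, long_path = NULL,
                                      wide_path = NULL) {
  if (!is.null(long_path)) .write_csv(pm$records, long_path)
  if (!is.null(wide_path)) {
    wide <- data.frame(compound = rownames(pm$delta),
                       signif(pm$delta, 6), check.names = FALSE)
    utils::write.csv(wide, wide_path, row.names = FALSE)
  }
  invisible(list(long = long_path, wide = wide_path))
}
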