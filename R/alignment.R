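#' Nucleotide alignments with tip dates
#'
#' An `alignment` holds equal-length upper-case nucleotide sequences (IUPAC
#' ambiguity codes and gaps allowed) together with a taxon table carrying per
#' taxon sampling times as heights (time before the latest sample).
#'
#' @name alignment
NULL

IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  "-" = c("A", "C", "G", "T"), "?" = c("A", "C", "G", "T"))

NUC <- c("A", "C", "G", "T")

make_alignment <- function(seqs, sampling_time = NULL) {
  if (anyDuplicated(names(seqs)))
    stop("duplicate taxon labels in alignment: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- toupper(unlist(seqs))
  len <- unname(nchar(seqs[1]))
  bad <- which(nchar(seqs) != len)
  if (length(bad))
    stop("ragged alignment: taxon '", names(seqs)[bad[1]], "' has length ",
         nchar(seqs)[bad[1]], ", expected ", len)
  if (is.null(sampling_time))
    sampling_time <- stats::setNames(rep(0, length(seqs)), names(seqs))
  structure(list(
    taxa = data.frame(label = names(seqs),
                      sampling_time = unname(sampling_time[names(seqs)]),
                      stringsAsFactors = FALSE),
    seqs = seqs, length = len), class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment: %d taxa, %d sites\n", nrow(x$taxa), x$length))
  invisible(x)
}

#' Read a nucleotide alignment from FASTA or NEXUS
#'
#' Tip sampling dates can be supplied either as a label suffix (the common
#' `name|2014.45` convention, set `date_sep`) or as a two-column tab-separated
#' table (label, time).  Dates are interpreted per `date_direction`:
#' `"forward"` values (for example decimal years) are converted to heights by
#' subtracting each date from the maximum, `"height"` values are used as is.
#'
#' @param path file path
#' @param format `"fasta"` or `"nexus"`
#' @param date_sep single character separating label from date, or `NULL`
#' @param date_table path of a two-column TSV (label, time), or `NULL`
#' @param date_direction `"forward"` or `"height"`
#' @return an `alignment`
#' @export
read_alignment <- function(path, format = c("fasta", "nexus"),
                           date_sep = NULL, date_table = NULL,
                           date_direction = c("forward", "height")) {
  format <- match.arg(format)
  date_direction <- match.arg(date_direction)
  if (format == "fasta") {
    dna <- ape::read.FASTA(path)
    seqs <- vapply(as.character(dna), function(ch) paste(ch, collapse = ""),
                   character(1))
  } else {
    dat <- ape::read.nexus.data(path)
    seqs <- vapply(dat, function(ch) paste(ch, collapse = ""), character(1))
  }
  names(seqs) <- trimws(names(seqs))
  times <- rep(0, length(seqs))
  names(times) <- names(seqs)
  if (!is.null(date_sep)) {
    parts <- strsplit(names(seqs), date_sep, fixed = TRUE)
    labs <- vapply(parts, function(p) paste(p[-length(p)], collapse = date_sep),
                   character(1))
    dates <- suppressWarnings(as.numeric(vapply(parts, function(p) p[length(p)],
                                                character(1))))
    if (any(is.na(dates))) stop("undated label(s): ",
                                paste(names(seqs)[is.na(dates)], collapse = ", "))
    names(seqs) <- labs
    times <- stats::setNames(dates, labs)
  } else if (!is.null(date_table)) {
    tab <- utils::read.table(date_table, sep = "\t", header = FALSE,
                             col.names = c("label", "time"),
                             stringsAsFactors = FALSE)
    times <- stats::setNames(tab$time, tab$label)
    missing <- setdiff(names(seqs), tab$label)
    if (length(missing)) stop("no date for taxa: ", paste(missing, collapse = ", "))
    times <- times[names(seqs)]
  }
  if (date_direction == "forward") {
    origin <- max(times)
    times <- origin - times
    if (any(times != 0))
      message("tip dates converted to heights relative to latest sample at ", origin)
  }
  make_alignment(seqs, times)
}

#' Write an alignment as FASTA
#'
#' @param aln an `alignment`
#' @param path output file
#' @export
write_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln$taxa)))
    writeLines(c(paste0(">", aln$taxa$label[i]), aln$seqs[[i]]), con)
  invisible(path)
}

#' Compress an alignment into unique site patterns
#'
#' A pattern is flagged invariant-capable for a nucleotide when that
#' nucleotide is compatible with every taxon's (possibly ambiguous) state in
#' the column; all-gap/all-ambiguous columns are capable for all four
#' nucleotides (gaps are missing data).  These flags drive the fast
#' proportion-of-invariable-sites likelihood path.
#'
#' @param aln an `alignment`
#' @return object of class `site_patterns`: a character matrix `states`
#'   (taxa x patterns), integer `weights` summing to the alignment length,
#'   and a 4 x npattern logical matrix `invariant_capable` (rows A,C,G,T)
#' @export
compress_patterns <- function(aln) {
  mat <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(mat) <- aln$taxa$label
  key <- apply(mat, 2, paste, collapse = "")
  uk <- unique(key)
  weights <- as.integer(table(factor(key, levels = uk)))
  states <- mat[, match(uk, key), drop = FALSE]
  cap <- vapply(seq_along(uk), function(j) {
    col <- states[, j]
    vapply(NUC, function(x)
      all(vapply(col, function(ch) x %in% IUPAC[[ch]], logical(1))), logical(1))
  }, logical(4))
  rownames(cap) <- NUC
  structure(list(states = states, weights = weights, invariant_capable = cap,
                 length = aln$length, taxa = aln$taxa),
            class = "site_patterns")
}

#' @export
print.site_patterns <- function(x, ...) {
  cat(sprintf("site_patterns: %d patterns over %d sites, %d taxa\n",
              length(x$weights), x$length, nrow(x$taxa)))
  invisible(x)
}
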