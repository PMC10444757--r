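#' Bovine rhodopsin reference sequence
#'
#' Opsin spectral tuning sites are conventionally reported in bovine rod
#' opsin (RH1) numbering; every sequence analysed here is first mapped onto
#' this 348-residue reference by global alignment.
#'
#' @return A single-element `Biostrings::AAStringSet`.
#' @export
bovine_rhodopsin <- function() {
  path <- system.file("extdata", "bovine_rh1.fasta", package = "dermopsin",
                      mustWork = TRUE)
  Biostrings::readAAStringSet(path)
}

#' Default SWS1 spectral tuning sites (bovine RH1 numbering)
#'
#' Thirteen residue positions at which substitutions are known to shift the
#' peak sensitivity of vertebrate SWS1 (short-wavelength-sensitive-1)
#' opsins. The set is assembled from the mutagenesis literature on SWS1
#' ultraviolet/violet tuning; it ships as an editable default rather than a
#' fixed constant, so analyses can swap in an alternative site list via the
#' `sites` arguments of the comparison functions.
#'
#' @return Sorted integer vector of 13 bovine positions.
#' @export
sws1_tuning_sites <- function() {
  sort(c(46L, 49L, 52L, 86L, 90L, 93L, 97L, 109L, 113L, 114L, 116L, 118L,
         265L))
}

#' Packaged SWS1 shift table
#'
#' Maps specific substitutions `(site, from, to)` to an interval of
#' lambda_max shift in nm. Shipped as a plain TSV under `extdata` so users
#' can extend it; see [read_shift_table()].
#'
#' @return Data frame with columns `site`, `from`, `to`, `shift_low_nm`,
#'   `shift_high_nm`.
#' @export
sws1_shift_table <- function() {
  read_shift_table(system.file("extdata", "sws1_tuning_shifts.tsv",
                               package = "dermopsin", mustWork = TRUE))
}

#' @rdname sws1_shift_table
#' @param path Path to a TSV with columns `site`, `from`, `to`,
#'   `shift_low_nm`, `shift_high_nm`; `#` lines are comments.
#' @export
read_shift_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("site", "from", "to", "shift_low_nm", "shift_high_nm")
  if (!all(need %in% names(df))) {
    stop("shift table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$shift_low_nm > df$shift_high_nm)) {
    stop("shift table has interval(s) with lower bound above upper bound")
  }
  df
}

AA_CANONICAL <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_protein <- function(x, what = "sequence") {
  res <- strsplit(toupper(x), "")[[1]]
  bad <- setdiff(unique(res), AA_CANONICAL)
  if (length(bad) > 0) {
    stop(what, " contains non-amino-acid character(s): ",
         paste(bad, collapse = ", "))
  }
  res
}

#' Map an opsin sequence onto bovine rhodopsin numbering
#'
#' Globally aligns a query amino-acid sequence against the bovine RH1
#' reference (Needleman-Wunsch with BLOSUM62 scoring, gap open 10 / extend
#' 1) and assigns every aligned query residue its bovine position. Ciliary
#' opsins are highly conserved, so the resulting numbering is robust to the
#' details of the scoring scheme.
#'
#' @param seq Query amino-acid sequence: a string, `AAString`, or a
#'   single-element `AAStringSet`.
#' @param reference Reference sequence (defaults to [bovine_rhodopsin()]).
#' @param id Identifier stored with the result (defaults to the FASTA name
#'   when available).
#' @return A `numbered_sequence`: data frame with columns `position`
#'   (query residue index), `residue`, and `bovine_pos` (`NA` for residues
#'   that align to a gap in the reference), with the query id as attribute
#'   `id`.
#' @export
map_to_bovine <- function(seq, reference = bovine_rhodopsin(), id = NULL) {
  if (methods::is(seq, "AAStringSet")) {
    if (is.null(id) && length(names(seq)) > 0) id <- names(seq)[[1]]
    seq <- as.character(seq[[1]])
  }
  seq <- as.character(seq)
  if (methods::is(reference, "AAStringSet")) {
    reference <- as.character(reference[[1]])
  }
  reference <- as.character(reference)
  if (nchar(seq) == 0 || nchar(reference) == 0) {
    stop("sequences must be non-empty")
  }
  check_protein(seq, "query")
  check_protein(reference, "reference")

  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(toupper(seq)),
    subject = Biostrings::AAString(toupper(reference)),
    type = "global",
    substitutionMatrix = get("BLOSUM62", envir = environment()),
    gapOpening = 10, gapExtension = 1)

  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  qi <- 0L
  si <- 0L
  pos <- integer(0)
  resid <- character(0)
  bpos <- integer(0)
  for (k in seq_along(p)) {
    if (p[k] != "-") qi <- qi + 1L
    if (s[k] != "-") si <- si + 1L
    if (p[k] != "-") {
      pos <- c(pos, qi)
      resid <- c(resid, p[k])
      bpos <- c(bpos, if (s[k] != "-") si else NA_integer_)
    }
  }
  out <- data.frame(position = pos, residue = resid, bovine_pos = bpos,
                    stringsAsFactors = FALSE)
  attr(out, "id") <- if (is.null(id)) "query" else id
  class(out) <- c("numbered_sequence", "data.frame")
  out
}

#' Residue at a bovine-numbered position
#'
#' @param ns A `numbered_sequence` from [map_to_bovine()].
#' @param bovine_pos Bovine position(s).
#' @return Character vector of residues; `NA` where the sequence has a gap
#'   at (or no residue mapped to) that position.
#' @export
residue_at <- function(ns, bovine_pos) {
  stopifnot(inherits(ns, "numbered_sequence"))
  idx <- match(bovine_pos, ns$bovine_pos)
  ifelse(is.na(idx), NA_character_, ns$residue[idx])
}

#' Call substitutions at spectral tuning sites
#'
#' Compares two bovine-numbered sequences at a set of tuning sites. Sites
#' where the residues differ become substitution records in `ref -> alt`
#' direction (`seq_a` supplies the reference residue); sites where either
#' sequence has a gap are reported separately as uncallable rather than as
#' substitutions.
#'
#' @param seq_a,seq_b `numbered_sequence` objects from [map_to_bovine()].
#' @param sites Integer vector of bovine positions
#'   (default [sws1_tuning_sites()]).
#' @return Data frame with columns `site`, `ref`, `alt`, `notation`
#'   (e.g. `"S97C"`), zero rows when the sequences agree everywhere;
#'   attribute `uncallable` holds the sites with a gap in either sequence.
#' @export
compare_tuning_sites <- function(seq_a, seq_b, sites = sws1_tuning_sites()) {
  stopifnot(inherits(seq_a, "numbered_sequence"),
            inherits(seq_b, "numbered_sequence"))
  ra <- residue_at(seq_a, sites)
  rb <- residue_at(seq_b, sites)
  uncallable <- sites[is.na(ra) | is.na(rb)]
  callable <- !is.na(ra) & !is.na(rb)
  hit <- callable & ra != rb
  out <- data.frame(site = sites[hit], ref = ra[hit], alt = rb[hit],
                    stringsAsFactors = FALSE)
  out$notation <- if (nrow(out) > 0) {
    paste0(out$ref, out$site, out$alt)
  } else {
    character(0)
  }
  attr(out, "uncallable") <- uncallable
  out
}

parse_substitutions <- function(subs) {
  if (is.data.frame(subs)) {
    stopifnot(all(c("site", "ref", "alt") %in% names(subs)))
    return(subs[, c("site", "ref", "alt")])
  }
  if (length(subs) == 0) {
    return(data.frame(site = integer(0), ref = character(0),
                      alt = character(0)))
  }
  m <- regmatches(subs, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", subs))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed substitution notation: ",
         paste(subs[bad], collapse = ", "),
         " (expected e.g. \"S97C\")")
  }
  data.frame(
    site = as.integer(vapply(m, `[`, "", 3L)),
    ref = toupper(vapply(m, `[`, "", 2L)),
    alt = toupper(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE)
}

#' Estimate SWS1 lambda_max by anchor-plus-shift
#'
#' Starts from the known lambda_max of a closely homologous anchor pigment
#' and accumulates the shift intervals of the observed tuning-site
#' substitutions. The reported interval is the anchor plus the summed shift
#' interval. The point estimate retains the anchor whenever a zero total
#' shift is consistent with the interval (the "centering on" rule: small
#' negative-leaning shifts do not move the centre), and falls back to the
#' interval midpoint otherwise.
#'
#' Substitutions absent from the shift table receive a zero-centred interval
#' of half-width `default_halfwidth_nm` (reflecting that known SWS1
#' tuning-site switches move lambda_max by at most a few nm) and are flagged
#' via a message as low-confidence.
#'
#' @param anchor_nm Anchor lambda_max in nm, within \[330, 650\].
#' @param subs Substitutions: character vector of notations (`"S97C"`) or a
#'   data frame with columns `site`, `ref`, `alt` (as returned by
#'   [compare_tuning_sites()]).
#' @param table Shift table (default [sws1_shift_table()]).
#' @param default_halfwidth_nm Half-width in nm for substitutions not in the
#'   table (default 3).
#' @return A `lambda_max_estimate`: list with `anchor_nm`, `substitutions`,
#'   `point_nm`, `interval_nm` (`c(low, high)`), and `in_sws1_range`
#'   (`TRUE` when the point lies in the vertebrate SWS1 span
#'   \[360, 440\] nm).
#' @export
#' @examples
#' est <- estimate_lambda_max(415, c("S97C", "M116V"))
#' est$point_nm      # 415
#' est$interval_nm   # c(411, 415)
estimate_lambda_max <- function(anchor_nm, subs = character(0),
                                table = sws1_shift_table(),
                                default_halfwidth_nm = 3) {
  stopifnot(length(anchor_nm) == 1, is.finite(anchor_nm),
            default_halfwidth_nm >= 0)
  if (anchor_nm < 330 || anchor_nm > 650) {
    stop("anchor lambda_max = ", anchor_nm,
         " nm outside the supported range [330, 650] nm")
  }
  subs <- parse_substitutions(subs)
  lo <- 0
  hi <- 0
  if (nrow(subs) > 0) {
    for (i in seq_len(nrow(subs))) {
      j <- which(table$site == subs$site[i] &
                 toupper(table$from) == subs$ref[i] &
                 toupper(table$to) == subs$alt[i])
      if (length(j) == 1) {
        lo <- lo + table$shift_low_nm[j]
        hi <- hi + table$shift_high_nm[j]
      } else {
        message("no published shift for ", subs$ref[i], subs$site[i],
                subs$alt[i], "; using low-confidence interval of +/-",
                default_halfwidth_nm, " nm")
        lo <- lo - default_halfwidth_nm
        hi <- hi + default_halfwidth_nm
      }
    }
  }
  interval <- anchor_nm + c(lo, hi)
  point <- if (lo <= 0 && hi >= 0) anchor_nm else anchor_nm + (lo + hi) / 2
  structure(
    list(anchor_nm = anchor_nm,
         substitutions = subs,
         point_nm = point,
         interval_nm = interval,
         in_sws1_range = point >= 360 && point <= 440),
    class = "lambda_max_estimate")
}

#' @export
print.lambda_max_estimate <- function(x, ...) {
  cat(sprintf(
    "lambda_max estimate: %.4g nm (interval [%.4g, %.4g] nm, anchor %.4g nm, %d substitution(s))\n",
    x$point_nm, x$interval_nm[1], x$interval_nm[2], x$anchor_nm,
    nrow(x$substitutions)))
  if (!x$in_sws1_range) {
    cat("NOTE: point estimate falls outside the vertebrate SWS1 range [360, 440] nm\n")
  }
  invisible(x)
}

#' Write a substitution report table
#'
#' Joins called substitutions with their shift intervals and writes a TSV
#' with columns `site`, `ref`, `alt`, `notation`, `shift_low_nm`,
#' `shift_high_nm` (shift columns `NA` for pairs absent from the table).
#'
#' @param subs Data frame from [compare_tuning_sites()].
#' @param path Output path.
#' @param table Shift table.
#' @return The report data frame, invisibly.
#' @export
write_substitution_report <- function(subs, path,
                                      table = sws1_shift_table()) {
  rep <- subs
  rep$shift_low_nm <- NA_real_
  rep$shift_high_nm <- NA_real_
  if (nrow(rep) > 0) {
    for (i in seq_len(nrow(rep))) {
      j <- which(table$site == rep$site[i] &
                 toupper(table$from) == rep$ref[i] &
                 toupper(table$to) == rep$alt[i])
      if (length(j) == 1) {
        rep$shift_low_nm[i] <- table$shift_low_nm[j]
        rep$shift_high_nm[i] <- table$shift_high_nm[j]
      }
    }
  }
  utils::write.table(rep, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(rep)
}
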