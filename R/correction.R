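# per-column coordinate maps of an alignment: 0-based ref/read position of
# the base in each column, NA at gap columns
alignment_maps <- function(alignment) {
  ar <- chars(alignment$aligned_read)
  af <- chars(alignment$aligned_ref)
  read_c <- ar != "-"
  ref_c <- af != "-"
  list(
    ar = ar, af = af,
    read_idx = ifelse(read_c, alignment$read_span[1] + cumsum(read_c) - 1L,
                      NA_integer_),
    ref_idx = ifelse(ref_c, alignment$ref_span[1] + cumsum(ref_c) - 1L,
                     NA_integer_)
  )
}

functionality_from_alignment <- function(alignment, ref,
                                         identity_floor = 0.6) {
  stopifnot(inherits(ref, "ab_reference"))
  if (alignment$identity_pct < identity_floor)
    return(structure(list(verdict = "no_alignment", in_frame = NA,
                          stop_codons = integer(0), conserved_ok = NA),
                     class = "functionality_call"))
  ev <- alignment$events
  net <- sum(ev$length[ev$event_type == "insertion"]) -
    sum(ev$length[ev$event_type == "deletion"])
  in_frame <- net %% 3L == 0L
  maps <- alignment_maps(alignment)

  # read coordinate where translation starts: the read base aligned at (or
  # first after) the reference frame offset
  start_cols <- which(!is.na(maps$ref_idx) &
                        maps$ref_idx >= ref$frame_offset &
                        !is.na(maps$read_idx))
  stop_codons <- integer(0)
  if (length(start_cols)) {
    r0 <- maps$read_idx[start_cols[1]]
    aa <- translate_dna(substr(alignment$read, r0 + 1L,
                               alignment$read_span[2]))
    stop_codons <- which(chars(aa) == "*")  # 1-based codon indices
  }

  conserved_ok <- NA
  cp <- ref$conserved_positions
  if (!is.null(cp) && nrow(cp)) {
    ok <- vapply(seq_len(nrow(cp)), function(k) {
      q <- ref$frame_offset + 3L * cp$codon[k] + 0:2
      cols <- match(q, maps$ref_idx)
      if (anyNA(cols)) return(FALSE)
      b <- maps$ar[cols]
      if (any(b == "-")) return(FALSE)
      translate_dna(collapse(b)) == cp$aa[k]
    }, logical(1))
    conserved_ok <- all(ok)
  }

  verdict <- if (length(stop_codons)) "stop_codon"
             else if (in_frame) "productive"
             else "unproductive"
  structure(list(verdict = verdict, in_frame = in_frame,
                 stop_codons = stop_codons, conserved_ok = conserved_ok),
            class = "functionality_call")
}

#' Call the functionality of an antibody read
#'
#' Aligns a sequence to its annotated reference and calls functionality the
#' way repertoire tools summarize it: \code{productive} (in-frame, no
#' premature stop codon), \code{unproductive} (net indel length not a
#' multiple of 3, without a stop), \code{stop_codon} (premature stop in the
#' translation, whatever the frame), or \code{no_alignment} (alignment
#' identity below \code{identity_floor} — unalignable artifact reads).
#' Whether the conserved framework Cys/Trp residues survive is reported in
#' \code{conserved_ok} but does not change the verdict.
#'
#' @param seq Nucleotide sequence (may contain "n" pads).
#' @param ref An [ab_reference()].
#' @param scoring A [scoring_scheme()].
#' @param identity_floor Identity fraction below which the read is called
#'   \code{no_alignment} (default 0.6).
#' @return \code{functionality_call}: verdict, in_frame, stop_codons
#'   (1-based codon indices), conserved_ok.
#' @examples
#' ref <- generate_reference(seed = 1)
#' assess_functionality(ref$seq, ref)$verdict
#' @export
assess_functionality <- function(seq, ref, scoring = scoring_scheme(),
                                 identity_floor = 0.6) {
  aln <- align_read(seq, ref, scoring)
  functionality_from_alignment(aln, ref, identity_floor)
}

#' @export
print.functionality_call <- function(x, ...) {
  cat("functionality:", x$verdict,
      if (length(x$stop_codons))
        sprintf("(stop at codon %s)",
                paste(x$stop_codons, collapse = ",")) else "",
      "\n")
  invisible(x)
}

#' Correct frameshift-causing indels in a read
#'
#' Two-pass reference-guided correction: the first alignment locates indel
#' events; detected insertions are excised from the read and detected
#' deletions are padded with the lowercase symbol "n" at their reference
#' coordinates, restoring the reference numbering; the corrected sequence
#' is then re-aligned and functionality re-called. Substitutions are never
#' altered — they are invisible to reference-frame restoration, which is
#' why in-frame substitution errors survive correction. Codons containing
#' a pad translate to "X", never to a stop.
#'
#' @param read Full-length read sequence.
#' @param ref An [ab_reference()].
#' @param scoring A [scoring_scheme()].
#' @param identity_floor Passed to the functionality call; reads below it
#'   are returned uncorrected as \code{no_alignment}.
#' @param read_id Identifier stored in the result.
#' @return \code{correction_result}: read_id, corrected_seq (same length as
#'   the reference for full-length reads), applied_edits (the indel events
#'   acted on), functionality_before / functionality_after, recovered
#'   (became productive through correction), uncorrectable_reason.
#' @examples
#' ref <- generate_reference(seed = 1)
#' read <- apply_events(ref$seq, data.frame(event_type = "insertion",
#'   ref_pos = 30L, ref_interval_end = 30L, length = 1L,
#'   bases = "G", ref_bases = ""))
#' correct_read(read, ref)$recovered
#' @export
correct_read <- function(read, ref, scoring = scoring_scheme(),
                         identity_floor = 0.6, read_id = "read") {
  aln1 <- align_read(read, ref, scoring, read_id = read_id)
  before <- functionality_from_alignment(aln1, ref, identity_floor)
  if (before$verdict == "no_alignment") {
    return(structure(
      list(read_id = read_id, corrected_seq = read,
           applied_edits = empty_events(),
           functionality_before = "no_alignment",
           functionality_after = "no_alignment",
           recovered = FALSE, uncorrectable_reason = "no_alignment"),
      class = "correction_result"))
  }
  maps <- alignment_maps(aln1)
  core <- ifelse(maps$af == "-", "",            # excise insertions
                 ifelse(maps$ar == "-", "n",    # pad deletions
                        maps$ar))
  corrected <- paste0(
    strrep("n", aln1$ref_span[1]),              # unaligned reference flanks
    collapse(core),
    strrep("n", aln1$ref_length - aln1$ref_span[2]))
  aln2 <- align_read(corrected, ref, scoring, read_id = read_id)
  after <- functionality_from_alignment(aln2, ref, identity_floor)
  edits <- aln1$events[aln1$events$event_type != "substitution", ,
                       drop = FALSE]
  structure(
    list(read_id = read_id, corrected_seq = corrected,
         applied_edits = edits,
         functionality_before = before$verdict,
         functionality_after = after$verdict,
         recovered = after$verdict == "productive" &&
           before$verdict != "productive",
         uncorrectable_reason = if (after$verdict == "productive")
           NA_character_ else after$verdict),
    class = "correction_result")
}

#' Correct a batch of reads
#'
#' @param reads Named character vector.
#' @param ref An [ab_reference()].
#' @param scoring A [scoring_scheme()].
#' @param identity_floor See [correct_read()].
#' @return List with \code{results} (list of \code{correction_result}),
#'   \code{table} (one row per read: n_edits, verdicts, recovered) and
#'   \code{corrected} (named character vector of corrected sequences).
#' @export
correct_reads <- function(reads, ref, scoring = scoring_scheme(),
                          identity_floor = 0.6) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%05d", seq_along(reads))
  results <- lapply(seq_along(reads), function(i)
    correct_read(reads[[i]], ref, scoring, identity_floor, read_id = ids[i]))
  table <- do.call(rbind, lapply(results, function(x)
    data.frame(read_id = x$read_id, n_edits = nrow(x$applied_edits),
               functionality_before = x$functionality_before,
               functionality_after = x$functionality_after,
               recovered = x$recovered)))
  list(results = results, table = table,
       corrected = setNames(vapply(results, `[[`, character(1),
                                   "corrected_seq"), ids))
}

#' Fraction of reads recovered by correction
#'
#' A read is recovered when correction turns a non-productive read into a
#' productive one. Reported against two denominators: all reads (the
#' convention of adding the recovered share to the productive row of a
#' functionality table) or erroneous reads only (reads that were either
#' non-productive before correction or had at least one edit applied).
#'
#' @param results List of \code{correction_result} (or the \code{results}
#'   element of [correct_reads()]).
#' @param denominator "total" or "erroneous".
#' @return Fraction in [0, 1].
#' @export
recovery_rate <- function(results, denominator = c("total", "erroneous")) {
  denominator <- match.arg(denominator)
  if (!is.null(results$results)) results <- results$results
  if (!length(results)) stop("empty correction result collection")
  rec <- vapply(results, `[[`, logical(1), "recovered")
  if (denominator == "total") return(mean(rec))
  err <- vapply(results, function(x)
    x$functionality_before != "productive" || nrow(x$applied_edits) > 0L,
    logical(1))
  if (!any(err)) return(0)
  sum(rec) / sum(err)
}

#' Functionality summary table before and after correction
#'
#' Mirrors the standard four-row functionality report (productive,
#' unproductive, stop codon, no rearrangement), as percentages of all
#' reads, before and after indel correction, with the recovered share
#' attached as the parenthetical conventionally printed next to the
#' productive row.
#'
#' @param correction Result of [correct_reads()].
#' @return Data frame with columns functionality, pct_before, pct_after;
#'   attribute \code{recovery_pct} carries the recovered share (% of all
#'   reads).
#' @export
functionality_summary <- function(correction) {
  tab <- correction$table
  verdicts <- c(productive = "productive", unproductive = "unproductive",
                stop_codon = "stop_codon", no_rearrangement = "no_alignment")
  out <- data.frame(
    functionality = names(verdicts),
    pct_before = vapply(verdicts, function(v)
      round(100 * mean(tab$functionality_before == v), 1), numeric(1)),
    pct_after = vapply(verdicts, function(v)
      round(100 * mean(tab$functionality_after == v), 1), numeric(1)),
    row.names = NULL)
  attr(out, "recovery_pct") <- round(100 * mean(tab$recovered), 1)
  out
}
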