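#' Assign an error event to a V-domain region
#'
#' Returns the label (FR1, CDR1, FR2, CDR2, FR3, CDR3) of the half-open
#' region interval containing the event's canonical position. Insertions
#' sitting exactly on a boundary belong to the region starting there.
#'
#' @param event One-row event data frame.
#' @param ref An [ab_reference()] with region annotation.
#' @param warn Warn when the position falls outside every region.
#' @return Region label, or NA with a warning when outside all regions.
#' @export
assign_region <- function(event, ref, warn = TRUE) {
  stopifnot(inherits(ref, "ab_reference"))
  p <- event$ref_pos[1]
  if (p < 0L || p > ref$length)
    stop("event position outside the reference span")
  rg <- ref$regions
  # an insertion before position L (or any event at a boundary) belongs to
  # the region starting at that position; half-open intervals do this
  hit <- which(rg$start <= p & p < rg$end)
  if (!length(hit) && event$event_type[1] == "insertion" && p == ref$length)
    hit <- nrow(rg)  # insertion at the very 3' end
  if (!length(hit)) {
    if (warn) warning("event position ", p, " outside all annotated regions")
    return(NA_character_)
  }
  rg$region[hit[1]]
}

#' Classify a read into an error category
#'
#' Applies the category rules used throughout: \code{accurate} (no events);
#' \code{single_insertion} (exactly one 1-nt insertion);
#' \code{multi_insertion} (insertions only, >= 2 nt inserted in total —
#' run extensions of 2-3 nt and multiple separate insertions both count
#' here); \code{single_deletion} / \code{single_substitution} (one 1-nt
#' event of that type and nothing else); \code{mixed} otherwise (two or
#' more distinct event types, or any multi-base deletion/substitution).
#' Also flags frameshifts (net inserted minus deleted nucleotides not a
#' multiple of 3) and premature stop codons in the read's translation.
#'
#' @param alignment A full-length \code{ab_alignment} (see
#'   [filter_full_length()]; partial alignments are an error).
#' @param ref The [ab_reference()] aligned against (frame and conserved
#'   annotation are used for the stop-codon flag).
#' @return List of class \code{read_classification}: read_id, category,
#'   n_events, total_nt_changed, frameshift, premature_stop, events.
#' @export
classify_read <- function(alignment, ref) {
  stopifnot(inherits(alignment, "ab_alignment"))
  if (!filter_full_length(alignment, ref))
    stop("alignment does not span the full reference; filter before classifying")
  ev <- alignment$events
  tp <- ev$event_type
  ins_nt <- sum(ev$length[tp == "insertion"])
  del_nt <- sum(ev$length[tp == "deletion"])
  total <- sum(ev$length)
  category <-
    if (nrow(ev) == 0L) "accurate"
    else if (all(tp == "insertion")) {
      if (ins_nt == 1L) "single_insertion" else "multi_insertion"
    }
    else if (nrow(ev) == 1L && tp == "deletion" && ev$length == 1L)
      "single_deletion"
    else if (nrow(ev) == 1L && tp == "substitution" && ev$length == 1L)
      "single_substitution"
    else "mixed"
  fun <- functionality_from_alignment(alignment, ref,
                                      identity_floor = 0)
  structure(
    list(read_id = alignment$read_id, category = category,
         n_events = nrow(ev), total_nt_changed = total,
         frameshift = (ins_nt - del_nt) %% 3L != 0L,
         premature_stop = length(fun$stop_codons) > 0L,
         events = ev),
    class = "read_classification"
  )
}

#' Align and classify a batch of reads
#'
#' Convenience wrapper: aligns every read against one reference, drops
#' reads that do not cover the full variable domain, and classifies the
#' rest.
#'
#' @param reads Named character vector of read sequences.
#' @param ref An [ab_reference()].
#' @param scoring A [scoring_scheme()].
#' @return List with \code{classifications} (data frame: read_id, category,
#'   n_events, total_nt_changed, frameshift, premature_stop),
#'   \code{events} (data frame of all events with read_id), \code{n_input},
#'   \code{n_full_length}, and \code{alignments} (list of
#'   \code{ab_alignment}).
#' @export
classify_reads <- function(reads, ref, scoring = scoring_scheme()) {
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%05d", seq_along(reads))
  alns <- lapply(seq_along(reads), function(i)
    align_read(reads[[i]], ref, scoring, read_id = ids[i]))
  keep <- vapply(alns, filter_full_length, logical(1), ref = ref)
  alns <- alns[keep]
  cls <- lapply(alns, classify_read, ref = ref)
  classifications <- do.call(rbind, lapply(cls, function(x)
    data.frame(read_id = x$read_id, category = x$category,
               n_events = x$n_events, total_nt_changed = x$total_nt_changed,
               frameshift = x$frameshift, premature_stop = x$premature_stop)))
  if (is.null(classifications))
    classifications <- data.frame(read_id = character(0),
                                  category = character(0),
                                  n_events = integer(0),
                                  total_nt_changed = integer(0),
                                  frameshift = logical(0),
                                  premature_stop = logical(0))
  events <- do.call(rbind, lapply(cls, function(x)
    if (nrow(x$events)) cbind(read_id = x$read_id, x$events) else NULL))
  if (is.null(events)) events <- cbind(read_id = character(0), empty_events())
  list(classifications = classifications, events = events,
       n_input = length(reads), n_full_length = sum(keep),
       alignments = alns)
}

#' Nucleotide composition difference between read and reference
#'
#' Per-base counts of the read minus the reference: the (dA, dG, dT, dC)
#' signature. A single inserted G gives dG = 1 with the other components
#' zero; components always sum to the read-minus-reference length
#' difference.
#'
#' @param read Read sequence.
#' @param ref Reference sequence string or [ab_reference()].
#' @return Named integer vector \code{c(dA, dG, dT, dC)}.
#' @export
composition_delta <- function(read, ref) {
  rs <- ref_seq_of(ref)
  cnt <- function(seq) {
    s <- chars(toupper(seq))
    vapply(c("A", "G", "T", "C"), function(b) sum(s == b), integer(1))
  }
  setNames(cnt(read) - cnt(rs), c("dA", "dG", "dT", "dC"))
}

# composition delta implied by an event list (no raw read needed)
delta_from_events <- function(events) {
  d <- c(dA = 0L, dG = 0L, dT = 0L, dC = 0L)
  if (is.null(events) || nrow(events) == 0L) return(d)
  key <- c(A = "dA", G = "dG", T = "dT", C = "dC")
  for (k in seq_len(nrow(events))) {
    for (b in chars(toupper(events$bases[k])))
      if (b %in% names(key)) d[key[[b]]] <- d[key[[b]]] + 1L
    for (b in chars(toupper(events$ref_bases[k])))
      if (b %in% names(key)) d[key[[b]]] <- d[key[[b]]] - 1L
  }
  d
}

#' Recurrent error signatures among erroneous reads
#'
#' Groups erroneous reads by their error signature and reports signatures
#' carried by at least \code{min_frac} of erroneous reads (default 0.5%),
#' sorted by frequency. The default signature combines the composition
#' difference vector with the canonical event positions; \code{by =
#' "composition"} groups on the (dA, dG, dT, dC) vector alone, the form in
#' which recurrence is usually plotted.
#'
#' @param batch Result of [classify_reads()] (or a list with
#'   \code{classifications} and \code{events} of the same shape).
#' @param min_frac Minimum share of erroneous reads (fraction).
#' @param by "position" (composition + event coordinates) or
#'   "composition".
#' @return Data frame: signature, n_reads, frac (of erroneous reads),
#'   sorted descending; zero rows when no read is erroneous.
#' @export
recurrent_signatures <- function(batch, min_frac = 0.005,
                                 by = c("position", "composition")) {
  by <- match.arg(by)
  cls <- batch$classifications
  err_ids <- cls$read_id[cls$category != "accurate"]
  empty <- data.frame(signature = character(0), n_reads = integer(0),
                      frac = numeric(0))
  if (!length(err_ids)) return(empty)
  ev_by_read <- split(batch$events, batch$events$read_id)
  sig <- vapply(err_ids, function(id) {
    ev <- ev_by_read[[id]]
    d <- delta_from_events(ev)
    comp <- paste(sprintf("%s=%+d", names(d), d), collapse = ",")
    if (by == "composition") return(comp)
    pos <- paste(sprintf("%s@%d", substr(ev$event_type, 1, 3), ev$ref_pos),
                 collapse = ";")
    paste(comp, pos, sep = "|")
  }, character(1))
  tab <- sort(table(sig), decreasing = TRUE)
  out <- data.frame(signature = names(tab), n_reads = as.integer(tab),
                    frac = as.numeric(tab) / length(err_ids))
  out[out$frac >= min_frac, , drop = FALSE]
}

# Table-3-style description of one indel event
describe_event <- function(ev) {
  if (ev$homopolymeric) {
    after <- if (ev$event_type == "insertion") ev$hp_len + ev$length
             else ev$hp_len - ev$length
    sprintf("%d%s in place of %d", after, ev$hp_base, ev$hp_len)
  } else {
    sprintf("%d random %s", ev$length,
            if (ev$event_type == "insertion") ev$bases else ev$ref_bases)
  }
}

describe_read_hp <- function(ev) {
  ins_del <- ev[ev$event_type != "substitution", , drop = FALSE]
  if (!nrow(ins_del)) return(list(hp = "", var = ""))
  hp_parts <- character(0)
  no_parts <- character(0)
  for (k in seq_len(nrow(ins_del))) {
    d <- describe_event(ins_del[k, ])
    if (ins_del$homopolymeric[k]) hp_parts <- c(hp_parts, d)
    else no_parts <- c(no_parts, d)
  }
  hp <- if (length(hp_parts) && length(no_parts))
    sprintf("yes: %s; no: %s", paste(hp_parts, collapse = "; "),
            paste(no_parts, collapse = "; "))
  else if (length(hp_parts))
    sprintf("yes: %s", paste(hp_parts, collapse = "; "))
  else "no"
  var_of <- function(type, label) {
    lens <- sort(ins_del$length[ins_del$event_type == type],
                 decreasing = TRUE)
    if (!length(lens)) return(character(0))
    sprintf("%s %s", paste(lens, collapse = " + "), label)
  }
  list(hp = hp,
       var = paste(c(var_of("insertion", "insertion"),
                     var_of("deletion", "deletion")), collapse = " + "))
}

#' Summarize the error profile of a classified read batch
#'
#' Builds the standard report tables: per-category read counts and
#' percentages; the per-region distribution of insertion events; the base
#' composition of all inserted nucleotides; a homopolymer table aggregating
#' indel-only reads by their run-context description (e.g. "yes: 4G in
#' place of 3" / "1 insertion"); and the recurrent-signature table.
#'
#' @param batch Result of [classify_reads()].
#' @param ref The [ab_reference()] used.
#' @param min_frac Recurrence threshold passed to
#'   [recurrent_signatures()].
#' @return List of class \code{profile_summary} with elements
#'   \code{categories}, \code{regions}, \code{inserted_bases},
#'   \code{homopolymer_table}, \code{signatures}, \code{n_reads}.
#' @export
summarize_profile <- function(batch, ref, min_frac = 0.005) {
  cls <- batch$classifications
  cats <- c("accurate", "single_insertion", "multi_insertion",
            "single_deletion", "single_substitution", "mixed")
  n <- vapply(cats, function(cc) sum(cls$category == cc), integer(1))
  categories <- data.frame(
    category = cats, n = n,
    pct = if (nrow(cls)) round(100 * n / nrow(cls), 1) else rep(0, 6))

  ev <- batch$events
  ins <- ev[ev$event_type == "insertion", , drop = FALSE]
  region_levels <- ref$regions$region
  reg <- ins$region[!is.na(ins$region)]
  regions <- data.frame(
    region = region_levels,
    n_insertions = vapply(region_levels, function(r) sum(reg == r),
                          integer(1)))

  ins_nt <- chars(collapse(ins$bases))
  inserted_bases <- data.frame(
    base = BASES,
    n = vapply(BASES, function(b) sum(ins_nt == b), integer(1)))
  inserted_bases$frac <- if (length(ins_nt))
    inserted_bases$n / length(ins_nt) else rep(NA_real_, 4)

  indel_only <- cls$read_id[cls$category %in%
    c("single_insertion", "multi_insertion", "single_deletion") |
    (cls$category == "mixed" & cls$read_id %in%
       setdiff(ev$read_id, ev$read_id[ev$event_type == "substitution"]))]
  hp_rows <- lapply(indel_only, function(id) {
    d <- describe_read_hp(ev[ev$read_id == id, , drop = FALSE])
    data.frame(hp_description = d$hp, variation = d$var)
  })
  homopolymer_table <- if (length(hp_rows)) {
    tab <- do.call(rbind, hp_rows)
    agg <- aggregate(list(n_reads = seq_len(nrow(tab))),
                     by = tab[c("hp_description", "variation")], FUN = length)
    agg[order(-agg$n_reads), c("n_reads", "hp_description", "variation")]
  } else {
    data.frame(n_reads = integer(0), hp_description = character(0),
               variation = character(0))
  }
  rownames(homopolymer_table) <- NULL

  structure(
    list(categories = categories, regions = regions,
         inserted_bases = inserted_bases,
         homopolymer_table = homopolymer_table,
         signatures = recurrent_signatures(batch, min_frac),
         n_reads = nrow(cls)),
    class = "profile_summary"
  )
}

#' @export
print.profile_summary <- function(x, ...) {
  cat("Error profile over", x$n_reads, "full-length reads\n\nCategories:\n")
  print(x$categories, row.names = FALSE)
  cat("\nInsertions by region:\n")
  print(x$regions, row.names = FALSE)
  cat("\nInserted-base composition:\n")
  print(x$inserted_bases, row.names = FALSE)
  cat("\nHomopolymer table (top rows):\n")
  print(head(x$homopolymer_table, 10), row.names = FALSE)
  invisible(x)
}
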