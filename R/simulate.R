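#' Simulation configuration for 454-style antibody reads
#'
#' Encodes the per-read error mixture and indel placement model used by
#' [simulate_reads()]. The defaults reproduce the error structure reported
#' for control-antibody pyrosequencing runs: about 60% error-free reads,
#' single-base insertions as the dominant error (~12%, ~20% together with
#' multi-insertions), deletions plus substitutions ~10%, mixed
#' multi-nucleotide variants ~10%, indels concentrated at short homopolymer
#' runs, and G accounting for over half of all inserted bases.
#'
#' @param p_accurate,p_single_ins,p_multi_ins,p_single_del,p_single_sub,p_mixed
#'   Category probabilities; must sum to 1 (tolerance 1e-9).
#' @param homopolymer_bias Probability that an indel is placed at a
#'   homopolymer run of length >= 2 (extending/shrinking the run) rather
#'   than at a uniformly random site.
#' @param insertion_base_probs Named probabilities (A,C,G,T) of the inserted
#'   base; must sum to 1. G-heavy by default.
#' @param hotspots Optional data frame with columns \code{pos} (0-based
#'   reference position), \code{base}, \code{weight}: homopolymer runs of
#'   \code{base} containing \code{pos} receive extra sampling weight,
#'   mimicking recurrent polyG hotspot errors.
#' @param n_reads Number of reads to simulate.
#' @param seed Integer seed for the simulator's private RNG stream.
#' @return A validated object of class \code{sim_config}.
#' @export
sim_config <- function(p_accurate = 0.60, p_single_ins = 0.12,
                       p_multi_ins = 0.08, p_single_del = 0.05,
                       p_single_sub = 0.05, p_mixed = 0.10,
                       homopolymer_bias = 0.8,
                       insertion_base_probs = c(A = 0.20, C = 0.20,
                                                G = 0.55, T = 0.05),
                       hotspots = NULL, n_reads = 5000L, seed = 1L) {
  p <- c(accurate = p_accurate, single_insertion = p_single_ins,
         multi_insertion = p_multi_ins, single_deletion = p_single_del,
         single_substitution = p_single_sub, mixed = p_mixed)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("category probabilities must be non-negative and sum to 1")
  if (homopolymer_bias < 0 || homopolymer_bias > 1)
    stop("homopolymer_bias must be in [0, 1]")
  ibp <- insertion_base_probs[BASES]
  if (anyNA(ibp) || any(ibp < 0) || abs(sum(ibp) - 1) > 1e-9)
    stop("insertion_base_probs must cover A,C,G,T and sum to 1")
  if (!is.null(hotspots) &&
      !all(c("pos", "base", "weight") %in% names(hotspots)))
    stop("hotspots needs columns pos, base, weight")
  if (n_reads < 0) stop("n_reads must be >= 0")
  structure(
    list(p = p, homopolymer_bias = homopolymer_bias,
         insertion_base_probs = ibp, hotspots = hotspots,
         n_reads = as.integer(n_reads), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_reads, "reads, seed", x$seed, "\n")
  cat("  mixture: ", paste(sprintf("%s=%.3g", names(x$p), x$p),
                           collapse = " "), "\n", sep = "")
  cat(sprintf("  homopolymer bias %.2f; inserted base probs %s\n",
              x$homopolymer_bias,
              paste(sprintf("%s=%.2f", names(x$insertion_base_probs),
                            x$insertion_base_probs), collapse = " ")))
  invisible(x)
}

#' Apply error events to a reference sequence
#'
#' Replays a set of events (in reference coordinates, the package-wide
#' convention: insertions occur before \code{ref_pos}; deletions and
#' substitutions cover the half-open interval
#' \code{[ref_pos, ref_interval_end)}) onto a sequence. Events must not
#' overlap. This is the ground-truth read constructor and the round-trip
#' oracle for alignment.
#'
#' @param seq Nucleotide string.
#' @param events Data frame with columns \code{event_type}, \code{ref_pos},
#'   \code{ref_interval_end}, \code{bases}.
#' @return The edited sequence.
#' @export
apply_events <- function(seq, events) {
  if (is.null(events) || nrow(events) == 0L) return(seq)
  ev <- events[order(-events$ref_pos), , drop = FALSE]
  s <- chars(seq)
  out <- s
  for (k in seq_len(nrow(ev))) {
    p <- ev$ref_pos[k]
    e <- ev$ref_interval_end[k]
    b <- ev$bases[k]
    out <- switch(
      ev$event_type[k],
      insertion = append(out, chars(b), after = p),
      deletion = if (e > p) out[-((p + 1L):e)] else out,
      substitution = {
        out[(p + 1L):e] <- chars(b)
        out
      },
      stop("unknown event type: ", ev$event_type[k])
    )
  }
  collapse(out)
}

empty_events <- function() {
  data.frame(event_type = character(0), ref_pos = integer(0),
             ref_interval_end = integer(0), length = integer(0),
             bases = character(0), ref_bases = character(0))
}

event_row <- function(type, pos, end, bases, ref_bases) {
  data.frame(event_type = type, ref_pos = as.integer(pos),
             ref_interval_end = as.integer(end),
             length = as.integer(max(nchar(bases), nchar(ref_bases))),
             bases = bases, ref_bases = ref_bases)
}

#' Simulate 454-style reads from a reference with ground truth
#'
#' Draws each read's error category independently from the configured
#' mixture, plants the corresponding events, and logs them in reference
#' coordinates. Indels are homopolymer-biased: with probability
#' \code{homopolymer_bias} an insertion extends (a deletion shrinks) a run
#' of length >= 2 whose base, for insertions, is drawn from
#' \code{insertion_base_probs}; otherwise the event lands at a uniformly
#' random interior site. All planted indels are left-normalized to the run
#' start so the truth log is directly comparable with canonical alignment
#' events. Events within a read are kept >= 6 nt apart so each is
#' unambiguously recoverable.
#'
#' Mixed reads carry 2-4 single-base events spanning at least two distinct
#' event types; multi-insertion reads carry 2-3 inserted nucleotides either
#' as one multi-base run extension or as separated single insertions.
#'
#' @param ref An [ab_reference()].
#' @param cfg A [sim_config()].
#' @return List with \code{reads} (named character vector) and \code{truth}
#'   (data frame: read_id, category, event_type, ref_pos, ref_interval_end,
#'   bases, ref_bases, hp_base, hp_len; accurate reads appear once with NA
#'   event fields).
#' @examples
#' ref <- generate_reference(seed = 1)
#' sim <- simulate_reads(ref, sim_config(n_reads = 20, seed = 7))
#' table(sim$truth$category[!duplicated(sim$truth$read_id)])
#' @export
simulate_reads <- function(ref, cfg) {
  stopifnot(inherits(ref, "ab_reference"), inherits(cfg, "sim_config"))
  L <- ref$length
  s <- chars(ref$seq)
  margin <- 3L
  runs <- homopolymer_runs(ref$seq)
  runs2 <- runs[runs$len >= 2L & runs$start >= margin &
                  runs$start + runs$len <= L - margin, , drop = FALSE]

  # per-run hotspot weights
  run_weight <- rep(1, nrow(runs2))
  if (!is.null(cfg$hotspots)) {
    for (h in seq_len(nrow(cfg$hotspots))) {
      hit <- runs2$base == cfg$hotspots$base[h] &
        runs2$start <= cfg$hotspots$pos[h] &
        cfg$hotspots$pos[h] < runs2$start + runs2$len
      run_weight[hit] <- run_weight[hit] + cfg$hotspots$weight[h]
    }
  }

  pick_run <- function(base, blocked) {
    ok <- runs2$start >= 0L
    if (!is.na(base)) ok <- ok & runs2$base == base
    if (length(blocked))
      ok <- ok & vapply(seq_len(nrow(runs2)), function(i)
        !any(seq(runs2$start[i], runs2$start[i] + runs2$len[i] - 1L)
             %in% blocked), logical(1))
    idx <- which(ok)
    if (!length(idx)) return(NA_integer_)
    if (length(idx) == 1L) return(idx)
    sample(idx, 1L, prob = run_weight[idx])
  }

  pick_pos <- function(blocked) {
    cand <- setdiff(seq(margin, L - margin - 1L), blocked)
    if (!length(cand)) stop("reference too short to place more events")
    if (length(cand) == 1L) cand else sample(cand, 1L)
  }

  block_span <- function(st, en) seq(st - 6L, en + 5L)

  make_insertion <- function(len, blocked) {
    b <- sample(BASES, 1L, prob = cfg$insertion_base_probs)
    run_i <- NA_integer_
    if (runif(1) < cfg$homopolymer_bias)
      run_i <- pick_run(b, blocked)
    if (!is.na(run_i)) {
      p <- runs2$start[run_i]
    } else {
      p <- pick_pos(blocked)
      while (p > 0L && s[p] == b) p <- p - 1L   # left-normalize
    }
    event_row("insertion", p, p, strrep(b, len), "")
  }

  make_deletion <- function(blocked) {
    run_i <- NA_integer_
    if (runif(1) < cfg$homopolymer_bias)
      run_i <- pick_run(NA, blocked)
    if (!is.na(run_i)) {
      p <- runs2$start[run_i]
    } else {
      p <- pick_pos(blocked)
      while (p > 0L && s[p] == s[p + 1L]) p <- p - 1L
    }
    event_row("deletion", p, p + 1L, "", s[p + 1L])
  }

  make_substitution <- function(blocked) {
    p <- pick_pos(blocked)
    b <- sample(setdiff(BASES, s[p + 1L]), 1L)
    event_row("substitution", p, p + 1L, b, s[p + 1L])
  }

  plant <- function(makers) {
    blocked <- integer(0)
    evs <- empty_events()
    for (mk in makers) {
      ev <- mk(blocked)
      evs <- rbind(evs, ev)
      blocked <- c(blocked, block_span(ev$ref_pos, ev$ref_interval_end))
    }
    evs[order(evs$ref_pos), , drop = FALSE]
  }

  events_for <- function(category) {
    switch(
      category,
      accurate = empty_events(),
      single_insertion = plant(list(function(b) make_insertion(1L, b))),
      multi_insertion = {
        total <- sample(2:3, 1L)
        if (runif(1) < 0.5) {
          plant(list(function(b) make_insertion(total, b)))
        } else {
          plant(rep(list(function(b) make_insertion(1L, b)), total))
        }
      },
      single_deletion = plant(list(make_deletion)),
      single_substitution = plant(list(make_substitution)),
      mixed = {
        n_ev <- sample(2:4, 1L)
        repeat {
          types <- sample(c("insertion", "deletion", "substitution"),
                          n_ev, replace = TRUE)
          if (length(unique(types)) >= 2L) break
        }
        plant(lapply(types, function(tp) switch(
          tp,
          insertion = function(b) make_insertion(1L, b),
          deletion = make_deletion,
          substitution = make_substitution
        )))
      }
    )
  }

  local_seed(cfg$seed, {
    cats <- if (cfg$n_reads > 0L)
      sample(names(cfg$p), cfg$n_reads, replace = TRUE, prob = cfg$p)
    else character(0)
    ids <- sprintf("read%05d", seq_len(cfg$n_reads))
    reads <- character(cfg$n_reads)
    truth_rows <- vector("list", cfg$n_reads)
    for (i in seq_len(cfg$n_reads)) {
      evs <- events_for(cats[i])
      reads[i] <- apply_events(ref$seq, evs)
      if (nrow(evs) == 0L) {
        truth_rows[[i]] <- data.frame(
          read_id = ids[i], category = cats[i], event_type = NA_character_,
          ref_pos = NA_integer_, ref_interval_end = NA_integer_,
          length = NA_integer_, bases = NA_character_,
          ref_bases = NA_character_, hp_base = NA_character_,
          hp_len = NA_integer_)
      } else {
        hp <- annotate_hp(ref$seq, evs)
        truth_rows[[i]] <- cbind(
          data.frame(read_id = ids[i], category = cats[i]),
          evs, hp_base = hp$hp_base, hp_len = hp$hp_len)
      }
    }
    names(reads) <- ids
    list(reads = reads, truth = do.call(rbind, truth_rows))
  })
}
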